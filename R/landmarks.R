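#' Controlled vocabulary of cephalometric landmark names
#'
#' Bilateral points carry `_R`/`_L` suffixes: porion (Po), lower orbital
#' point (Or), pterygoid fovea (FP), condylion (Cd), gonion (Go); midline
#' points are A, B, N (nasion), Ans/Pns (anterior/posterior nasal spine)
#' and Me (menton). Other names are accepted by readers but flagged.
#'
#' @export
CEPH_LANDMARKS <- c("Po_R", "Po_L", "Or_R", "Or_L", "FP_R", "FP_L",
                    "Cd_R", "Cd_L", "A", "B", "N", "Ans", "Pns", "Me",
                    "Go_R", "Go_L")

#' Named anatomical landmarks in world coordinates
#'
#' Stored as an n x 3 matrix (mm, same world frame as the volume affine)
#' with landmark names as row names.
#'
#' @param ... Either named length-3 numeric vectors
#'   (`landmark_set(Me = c(0, -10, -80), ...)`), or a single n x 3 matrix /
#'   data frame with row names.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && (is.matrix(args[[1]]) || is.data.frame(args[[1]])) &&
      is.null(names(args))) {
    m <- as.matrix(args[[1]])
  } else {
    if (is.null(names(args)) || any(names(args) == "")) {
      stop("all landmarks must be named", call. = FALSE)
    }
    m <- do.call(rbind, args)
    rownames(m) <- names(args)
  }
  if (ncol(m) != 3L) stop("landmarks must have 3 coordinates", call. = FALSE)
  if (is.null(rownames(m))) stop("landmarks must be named", call. = FALSE)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop("landmark coordinates must be finite numbers", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    dups <- unique(rownames(m)[duplicated(rownames(m))])
    stop(sprintf("duplicate landmark name(s): %s",
                 paste(dups, collapse = ", ")), call. = FALSE)
  }
  colnames(m) <- c("x", "y", "z")
  class(m) <- c("landmark_set", class(m))
  m
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d point(s) (mm, world frame)\n", nrow(x)))
  print(format(round(unclass(x), 3)), quote = FALSE)
  invisible(x)
}

#' Fetch required landmarks, failing fast when absent
#'
#' @param lm A `landmark_set`.
#' @param names Character vector of required landmark names.
#' @return Matrix of the requested points (rows in the requested order).
#' @export
require_landmarks <- function(lm, names) {
  missing <- setdiff(names, rownames(lm))
  if (length(missing) > 0L) {
    stop(sprintf("missing landmark %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unclass(lm)[names, , drop = FALSE]
}

lm_point <- function(lm, name) as.vector(require_landmarks(lm, name))

has_landmarks <- function(lm, names) all(names %in% rownames(lm))

#' Read landmarks from CSV or JSON
#'
#' CSV files must have a `name,x,y,z` header; JSON files map landmark names
#' to `[x, y, z]` arrays. Coordinates are world mm in the same frame as the
#' volume affine. Names outside the controlled vocabulary are accepted but
#' reported via a message.
#'
#' @param path Path to a `.csv` or `.json` landmark file.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file does not exist: %s", path), call. = FALSE)
  }
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nm <- names(obj)
    coords <- do.call(rbind, lapply(obj, function(v) {
      if (length(v) != 3L || !is.numeric(v)) {
        stop("each JSON landmark must be a numeric [x, y, z] triple",
             call. = FALSE)
      }
      as.numeric(v)
    }))
    rownames(coords) <- nm
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop(sprintf("landmark CSV must have columns %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    for (col in c("x", "y", "z")) {
      if (!is.numeric(df[[col]])) {
        stop(sprintf("non-numeric coordinate in column '%s'", col),
             call. = FALSE)
      }
    }
    coords <- as.matrix(df[, c("x", "y", "z")])
    rownames(coords) <- df$name
  }
  if (anyDuplicated(rownames(coords))) {
    dups <- unique(rownames(coords)[duplicated(rownames(coords))])
    stop(sprintf("duplicate landmark name(s): %s",
                 paste(dups, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(rownames(coords), CEPH_LANDMARKS)
  if (length(unknown) > 0L) {
    message(sprintf("accepting landmark name(s) outside the standard set: %s",
                    paste(unknown, collapse = ", ")))
  }
  landmark_set(coords)
}

#' Write landmarks to CSV or JSON
#'
#' @param lm A `landmark_set`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  if (grepl("\\.json$", path)) {
    obj <- stats::setNames(
      lapply(seq_len(nrow(lm)), function(i) as.numeric(unclass(lm)[i, ])),
      rownames(lm))
    jsonlite::write_json(obj, path, digits = NA)
  } else {
    df <- data.frame(name = rownames(lm), x = unclass(lm)[, 1],
                     y = unclass(lm)[, 2], z = unclass(lm)[, 3])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Apply a rigid motion to every landmark
#'
#' Same convention as [resample_rigid()]:
#' `T(x) = R (x - center) + center + translation`.
#'
#' @param lm A `landmark_set`.
#' @param rotation 3x3 rotation matrix.
#' @param center Pivot point (world mm); default origin.
#' @param translation Length-3 translation (mm).
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, rotation, center = c(0, 0, 0),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(lm, "landmark_set"))
  m <- sweep(unclass(lm), 2L, center) %*% t(rotation) +
    rep(center + translation, each = nrow(lm))
  rownames(m) <- rownames(lm)
  landmark_set(m)
}
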