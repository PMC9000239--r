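#' Three-way data cube
#'
#' Container for a data cube `X(I, J, K)`: `I` elution / flow-time points,
#' `J` spectral channels (wavelengths or m/z), and `K` slices (samples or
#' chromatographic runs). Every slice `X_k` is an `I x J` matrix; all slices
#' share the same time and channel axes.
#'
#' @param values numeric array of dimension `c(I, J, K)`, or a list of `K`
#'   `I x J` matrices of identical shape.
#' @param time_axis numeric or character labels for the first mode
#'   (length `I`); defaults to `1:I`.
#' @param channel_axis labels for the second mode (length `J`);
#'   defaults to `1:J`.
#' @param slice_ids labels for the third mode (length `K`);
#'   defaults to `1:K`.
#'
#' @return An object of class `three_way_array` with elements `values`
#'   (the `I x J x K` array), `time_axis`, `channel_axis`, `slice_ids`.
#' @examples
#' X <- three_way_array(array(1:8, c(2, 2, 2)))
#' dim(X$values)
#' @export
three_way_array <- function(values, time_axis = NULL, channel_axis = NULL,
                            slice_ids = NULL) {
  if (is.list(values)) {
    shapes <- vapply(values, dim, integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
      stop("all slices must have identical (I, J) shape; got ",
           paste(apply(shapes, 2, paste, collapse = "x"), collapse = ", "))
    }
    values <- array(unlist(values, use.names = FALSE),
                    c(shapes[1, 1], shapes[2, 1], length(values)))
  }
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) {
    stop("'values' must be a 3-dimensional array or a list of matrices")
  }
  if (!all(is.finite(values))) stop("all cube values must be finite")
  d <- dim(values)
  if (any(d < 1L)) stop("I, J, K must all be >= 1")
  if (is.null(time_axis)) time_axis <- seq_len(d[1])
  if (is.null(channel_axis)) channel_axis <- seq_len(d[2])
  if (is.null(slice_ids)) slice_ids <- seq_len(d[3])
  if (length(time_axis) != d[1]) {
    stop("time_axis length (", length(time_axis), ") != I (", d[1], ")")
  }
  if (length(channel_axis) != d[2]) {
    stop("channel_axis length (", length(channel_axis), ") != J (", d[2], ")")
  }
  if (length(slice_ids) != d[3]) {
    stop("slice_ids length (", length(slice_ids), ") != K (", d[3], ")")
  }
  structure(list(values = values, time_axis = time_axis,
                 channel_axis = channel_axis, slice_ids = slice_ids),
            class = "three_way_array")
}

#' @export
print.three_way_array <- function(x, ...) {
  d <- dim(x$values)
  cat("three_way_array: ", d[1], " times x ", d[2], " channels x ",
      d[3], " slices\n", sep = "")
  invisible(x)
}

#' @export
dim.three_way_array <- function(x) dim(x$values)

.aug_modes <- c("columnwise", "rowwise", "slicewise")

#' Augment a three-way cube into a two-way matrix
#'
#' Reshapes the cube into one of the three augmented data matrices used in
#' multiset curve resolution: `columnwise` stacks the slices vertically
#' (`(I*K) x J`, all slices share the spectral column space), `rowwise`
#' concatenates them horizontally (`I x (J*K)`), and `slicewise` places the
#' vectorized slice `vec(X_k)` as row `k` (`K x (I*J)`). The slicewise
#' vectorization is time-major: all channels of time 1, then time 2, and so
#' on.
#'
#' @param X a [three_way_array].
#' @param mode one of `"columnwise"`, `"rowwise"`, `"slicewise"`.
#' @return An object of class `augmented_matrix`: a list with `values`
#'   (the matrix), `mode`, and `origin_dims = c(I, J, K)`.
#' @seealso [unfold_augmented()] for the exact inverse.
#' @examples
#' X <- three_way_array(array(1:8, c(2, 2, 2)))
#' augment(X, "columnwise")$values
#' @export
augment <- function(X, mode = c("columnwise", "rowwise", "slicewise")) {
  stopifnot(inherits(X, "three_way_array"))
  if (length(mode) == 1L && !mode %in% .aug_modes) {
    stop("unknown augmentation mode '", mode, "'; valid modes are: ",
         paste(.aug_modes, collapse = ", "))
  }
  mode <- match.arg(mode)
  v <- X$values
  d <- dim(v)
  I <- d[1]; J <- d[2]; K <- d[3]
  m <- switch(mode,
    columnwise = {
      out <- matrix(0, I * K, J)
      for (k in seq_len(K)) out[(k - 1L) * I + seq_len(I), ] <- v[, , k]
      out
    },
    rowwise = matrix(v, I, J * K),
    slicewise = {
      out <- matrix(0, K, I * J)
      for (k in seq_len(K)) out[k, ] <- as.vector(t(v[, , k]))
      out
    })
  structure(list(values = m, mode = mode, origin_dims = d),
            class = "augmented_matrix")
}

#' Unfold an augmented matrix back into the original cube
#'
#' Exact inverse of [augment()]: reconstructs the `I x J x K` cube from the
#' augmented matrix and its recorded origin dimensions.
#'
#' @param A an `augmented_matrix` (or a plain matrix, in which case `mode`
#'   and `origin_dims` must be supplied).
#' @param mode,origin_dims override/supply the augmentation metadata.
#' @return A [three_way_array] with default axis labels.
#' @export
unfold_augmented <- function(A, mode = NULL, origin_dims = NULL) {
  if (inherits(A, "augmented_matrix")) {
    if (is.null(mode)) mode <- A$mode
    if (is.null(origin_dims)) origin_dims <- A$origin_dims
    A <- A$values
  }
  if (is.null(mode) || is.null(origin_dims)) {
    stop("mode and origin_dims are required for a plain matrix")
  }
  if (!mode %in% .aug_modes) {
    stop("unknown augmentation mode '", mode, "'; valid modes are: ",
         paste(.aug_modes, collapse = ", "))
  }
  I <- origin_dims[1]; J <- origin_dims[2]; K <- origin_dims[3]
  v <- array(0, c(I, J, K))
  if (mode == "columnwise") {
    stopifnot(nrow(A) == I * K, ncol(A) == J)
    for (k in seq_len(K)) v[, , k] <- A[(k - 1L) * I + seq_len(I), , drop = FALSE]
  } else if (mode == "rowwise") {
    stopifnot(nrow(A) == I, ncol(A) == J * K)
    v <- array(A, c(I, J, K))
  } else {
    stopifnot(nrow(A) == K, ncol(A) == I * J)
    for (k in seq_len(K)) v[, , k] <- t(matrix(A[k, ], J, I))
  }
  three_way_array(v)
}

#' Fold an augmented concentration profile into an I x K matrix
#'
#' The augmented concentration profile of one component, `c_aug_n`
#' (length `I*K`, slices stacked vertically), is folded so that column `k`
#' holds the component's elution profile in slice `k`. This is the folding
#' on which the trilinearity constraint operates.
#'
#' @param c_aug_n numeric vector of length `I * K`.
#' @param I,K dimensions of the fold.
#' @return `I x K` numeric matrix.
#' @seealso [unfold_component_profile()]
#' @examples
#' fold_component_profile(c(1, 2, 3, 4), I = 2, K = 2)
#' @export
fold_component_profile <- function(c_aug_n, I, K) {
  c_aug_n <- as.numeric(c_aug_n)
  if (length(c_aug_n) != I * K) {
    stop("profile length ", length(c_aug_n), " != I*K = ", I * K)
  }
  matrix(c_aug_n, nrow = I, ncol = K)
}

#' Unfold an I x K component profile matrix back to a vector
#'
#' Exact inverse of [fold_component_profile()].
#'
#' @param C_n `I x K` matrix (column k = profile in slice k).
#' @return Numeric vector of length `I * K`.
#' @export
unfold_component_profile <- function(C_n) {
  as.vector(as.matrix(C_n))
}

#' Read a three-way dataset from slice files and a JSON manifest
#'
#' The manifest is a JSON object with fields `slices` (paths to delimited
#' numeric matrices, one per slice, relative to the manifest directory),
#' and optional `time_axis`, `channel_axis`, `slice_ids`, `sep`, `header`.
#' Each slice file holds an `I x J` matrix (rows = times, columns =
#' channels) with no header by default.
#'
#' @param manifest_path path to the JSON manifest.
#' @return A [three_way_array].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$slices) || length(man$slices) < 1L) {
    stop("manifest ", manifest_path, " lists no slices")
  }
  base <- dirname(manifest_path)
  sep <- if (is.null(man$sep)) "\t" else man$sep
  header <- isTRUE(man$header)
  slices <- vector("list", length(man$slices))
  for (k in seq_along(man$slices)) {
    p <- file.path(base, man$slices[[k]])
    if (!file.exists(p)) stop("slice file missing: ", p, " (slice ", k, ")")
    m <- tryCatch(
      as.matrix(utils::read.table(p, sep = sep, header = header,
                                  colClasses = "numeric")),
      error = function(e) stop("non-numeric or malformed data in ", p, ": ",
                               conditionMessage(e), call. = FALSE))
    slices[[k]] <- unname(m)
  }
  shapes <- vapply(slices, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    bad <- which(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])[1]
    stop("slice ", bad, " (", man$slices[[bad]], ") has shape ",
         shapes[1, bad], "x", shapes[2, bad], " but slice 1 has ",
         shapes[1, 1], "x", shapes[2, 1])
  }
  three_way_array(slices,
                  time_axis = man$time_axis,
                  channel_axis = man$channel_axis,
                  slice_ids = man$slice_ids)
}

#' Write a three-way dataset as slice files plus a JSON manifest
#'
#' @param X a [three_way_array].
#' @param dir_path output directory (created if needed).
#' @param sep field separator for the slice files (default tab).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(X, dir_path, sep = "\t") {
  stopifnot(inherits(X, "three_way_array"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  K <- dim(X$values)[3]
  files <- sprintf("slice_%03d.tsv", seq_len(K))
  for (k in seq_len(K)) {
    utils::write.table(
      format(X$values[, , k], digits = 17, scientific = TRUE, trim = TRUE),
      file.path(dir_path, files[k]),
      sep = sep, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  man <- list(slices = files,
              time_axis = X$time_axis,
              channel_axis = X$channel_axis,
              slice_ids = X$slice_ids,
              sep = sep, header = FALSE)
  path <- file.path(dir_path, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
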