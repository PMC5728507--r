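# Seeded synthetic data generators for the two study regimes — dense
# pixel-like classification matrices on [0,1] and high-dimensional low-rank
# molecular-descriptor regression matrices on (0,1) — plus unit scaling,
# PCA reduction, and readers/writers for CSV and IDX files.

new_dataset <- function(features, targets, task, feature_scale) {
  structure(
    list(features = features, targets = targets, task = task,
         feature_scale = feature_scale),
    class = "nn_dataset"
  )
}

#' @export
print.nn_dataset <- function(x, ...) {
  cat(sprintf("Dataset (%s): %d samples x %d features, scale %s\n",
              x$task, nrow(x$features), ncol(x$features), x$feature_scale))
  invisible(x)
}

#' Generate a pixel-like classification dataset
#'
#' Gaussian class clusters with controllable separation: class centers are
#' random directions scaled to length `separation`, samples add unit-variance
#' noise, and every feature column is min-max scaled to [0, 1] — a stand-in
#' with the statistical shape of dense image data.  Classes are near-balanced
#' (the first `n %% n_classes` classes get one extra sample).
#'
#' @param n Number of samples (>= 10 per class).
#' @param d Number of features (>= 2).
#' @param n_classes Number of classes.
#' @param separation Distance of each class center from the origin, in noise
#'   standard deviations; around 4 gives a task a linear model solves almost
#'   perfectly, 1-2 gives a genuinely hard task.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return An `nn_dataset` with `features` (n x d matrix in [0, 1]),
#'   `labels` in `targets` as 1-based integers, `task = "classification"`.
#' @export
make_classification_data <- function(n, d, n_classes, separation = 4,
                                     seed = 1L) {
  n <- as.integer(n); d <- as.integer(d); n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  if (n < 10L * n_classes) {
    stop("need at least 10 samples per class", call. = FALSE)
  }
  if (d < 2L) stop("'d' must be >= 2", call. = FALSE)
  stopifnot_scalar_number(separation, "separation", 0)

  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_classes * d), nrow = n_classes)
    centers <- centers / sqrt(rowSums(centers^2)) * separation
    base <- n %/% n_classes
    counts <- rep(base, n_classes) + (seq_len(n_classes) <= n %% n_classes)
    labels <- sample(rep(seq_len(n_classes), counts))
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d), nrow = n)
    x <- scale_unit(x, "min_max")
    new_dataset(x, as.integer(labels), "classification", "unit_interval")
  })
}

#' Generate a high-dimensional QSAR-style descriptor regression dataset
#'
#' Emulates molecular-descriptor bioactivity data: a thin latent factor
#' matrix (n x latent_rank) times sparse loadings plus Gaussian noise gives
#' a descriptor matrix that is PCA-reducible to roughly `latent_rank`
#' components; the activity is a nonlinear (quadratic plus interaction)
#' function of the first three latent factors plus noise, so a network with
#' hidden layers can fit it but a linear model cannot.  Descriptors are
#' scaled into the open interval (0, 1).
#'
#' @param n_molecules,n_descriptors Matrix shape (samples x features).
#' @param latent_rank Number of latent factors,
#'   `< min(n_molecules, n_descriptors)`.
#' @param noise_sd Standard deviation of descriptor and activity noise.
#' @param seed Integer seed.
#' @return An `nn_dataset` with `task = "regression"`, activity values in
#'   `targets`, and the latent factor matrix attached as attribute
#'   `"latent"` for recoverability checks.
#' @export
make_qsar_data <- function(n_molecules, n_descriptors, latent_rank = 10L,
                           noise_sd = 0.1, seed = 1L) {
  n <- as.integer(n_molecules); d <- as.integer(n_descriptors)
  r <- as.integer(latent_rank)
  if (r >= min(n, d)) {
    stop("'latent_rank' must be below min(n_molecules, n_descriptors)",
         call. = FALSE)
  }
  if (r < 3L) stop("'latent_rank' must be >= 3 (the activity depends on 3 factors)",
                   call. = FALSE)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)

  with_seed(seed, {
    z <- matrix(stats::rnorm(n * r), nrow = n)
    # sparse loadings: each descriptor draws on 1-3 random latent factors
    loadings <- matrix(0, nrow = r, ncol = d)
    for (j in seq_len(d)) {
      k <- sample(1:3, 1L)
      rows <- sample.int(r, k)
      loadings[rows, j] <- stats::rnorm(k)
    }
    x <- z %*% loadings
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(n * d, sd = noise_sd),
                                      nrow = n)
    # map each column into the open unit interval
    x <- scale_unit(x, "min_max") * 0.998 + 0.001

    activity <- 10 + z[, 1]^2 + 0.5 * z[, 2] * z[, 3] + z[, 1] - 0.5 * z[, 2]
    if (noise_sd > 0) activity <- activity + stats::rnorm(n, sd = noise_sd)
    out <- new_dataset(x, activity, "regression", "open_unit_interval")
    attr(out, "latent") <- z
    out
  })
}

#' Scale features onto the unit interval
#'
#' `divide_255` maps pixel intensities x in [0, 255] to x/255; `min_max`
#' maps each feature column onto [0, 1] (constant columns become 0).
#'
#' @param features Numeric matrix.
#' @param mode `"min_max"` or `"divide_255"`.
#' @return The scaled matrix.
#' @examples
#' scale_unit(matrix(c(2, 4, 6)), "min_max")   # 0, 0.5, 1
#' @export
scale_unit <- function(features, mode = c("min_max", "divide_255")) {
  mode <- match.arg(mode)
  x <- as_feature_matrix(features)
  if (mode == "divide_255") {
    if (any(x < 0) || any(x > 255)) {
      stop("divide_255 requires values in [0, 255]", call. = FALSE)
    }
    return(x / 255)
  }
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  range <- maxs - mins
  range[range == 0] <- 1          # constant columns map to 0
  sweep(sweep(x, 2L, mins, "-"), 2L, range, "/")
}

#' Project features onto their top principal components
#'
#' Centers the feature matrix and projects it onto the top-k principal
#' axes.  With `k = NULL`, k is chosen as the smallest component count whose
#' cumulative explained variance reaches `var_threshold` (default 95%).
#'
#' @param features Numeric matrix, samples x features.
#' @param k Component count, or `NULL` to choose by explained variance.
#' @param var_threshold Cumulative explained-variance target used when
#'   `k = NULL`.
#' @return A list with `scores` (samples x k), `explained_variance`
#'   (fractions for the k kept components, non-increasing), `rotation` and
#'   `center` (to project new data), and `k`.
#' @export
pca_reduce <- function(features, k = NULL, var_threshold = 0.95) {
  x <- as_feature_matrix(features)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  max_k <- length(p$sdev)
  if (is.null(k)) {
    k <- which(cumsum(frac) >= var_threshold)[1L]
    if (is.na(k)) k <- max_k
  }
  k <- as.integer(k)
  if (k < 1L || k > max_k) {
    stop(sprintf("'k' must lie in 1..%d", max_k), call. = FALSE)
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained_variance = frac[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       center = p$center, k = k)
}

#' Read / write a dataset as CSV
#'
#' The CSV has a header row, one feature per column, and one label/target
#' column (default name `"label"`).  Classification labels are stored as
#' integers.
#'
#' @param dataset An `nn_dataset`.
#' @param path CSV file path.
#' @param label_col Name of the label/target column.
#' @param task Task of the data being read, `"classification"` or
#'   `"regression"`.
#' @return `path` invisibly (write); an `nn_dataset` (read).
#' @export
write_dataset_csv <- function(dataset, path, label_col = "label") {
  stopifnot(inherits(dataset, "nn_dataset"))
  df <- as.data.frame(dataset$features)
  df[[label_col]] <- dataset$targets
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, label_col = "label",
                             task = c("classification", "regression")) {
  task <- match.arg(task)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df)) {
    stop(sprintf("column '%s' not found in %s", label_col, path),
         call. = FALSE)
  }
  targets <- df[[label_col]]
  features <- as.matrix(df[setdiff(names(df), label_col)])
  storage.mode(features) <- "double"
  if (task == "classification") targets <- as.integer(targets)
  scale <- if (all(features >= 0 & features <= 1)) "unit_interval"
           else "unscaled"
  new_dataset(features, targets, task, scale)
}

#' Read an IDX (MNIST-dialect) array file
#'
#' Parses the IDX binary layout: a 4-byte magic number whose third byte
#' gives the element type and fourth byte the number of dimensions, followed
#' by big-endian 32-bit dimension sizes and the row-major payload.  The file
#' header — not any external description — determines the array shape.
#' Supported element types: unsigned byte (0x08), signed byte (0x09),
#' 32-bit integer (0x0C), single (0x0D) and double (0x0E) floats.
#'
#' @param path Path to an IDX file.
#' @return A numeric array with the dimensions declared in the header.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (magic[1] != 0L || magic[2] != 0L) {
    stop("not an IDX file: bad magic number", call. = FALSE)
  }
  type_code <- magic[3]
  ndims <- magic[4]
  dims <- readBin(con, "integer", n = ndims, size = 4L, endian = "big")
  n_total <- prod(dims)
  values <- switch(as.character(type_code),
    "8"  = readBin(con, "integer", n = n_total, size = 1L, signed = FALSE),
    "9"  = readBin(con, "integer", n = n_total, size = 1L, signed = TRUE),
    "12" = readBin(con, "integer", n = n_total, size = 4L, endian = "big"),
    "13" = readBin(con, "numeric", n = n_total, size = 4L, endian = "big"),
    "14" = readBin(con, "numeric", n = n_total, size = 8L, endian = "big"),
    stop(sprintf("unsupported IDX element type 0x%02X", type_code),
         call. = FALSE)
  )
  if (length(values) != n_total) {
    stop("IDX payload shorter than its header declares", call. = FALSE)
  }
  # IDX is row-major (last dimension fastest); R arrays are column-major
  array(as.numeric(values), dim = rev(dims)) |> aperm(rev(seq_len(ndims)))
}

#' Flatten an IDX image array into a feature matrix
#'
#' Turns an images x rows x cols array (as returned by [read_idx()]) into a
#' samples x pixels matrix, one image per row.
#'
#' @param images A 3-dimensional numeric array.
#' @return A numeric matrix with `dim(images)[1]` rows.
#' @export
idx_to_features <- function(images) {
  d <- dim(images)
  if (length(d) != 3L) stop("'images' must be a 3-d array", call. = FALSE)
  # aperm so that, per image, columns vary fastest: row-major pixel order
  matrix(aperm(images, c(3L, 2L, 1L)), nrow = d[1], byrow = TRUE)
}
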