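#' Standardize an RGB image per color channel
#'
#' Each channel is shifted and scaled to sample mean 0 and standard
#' deviation 1 (population, 1/N convention). A constant channel — e.g. a
#' blank TMA margin — maps to all zeros rather than erroring.
#'
#' @param image H x W x 3 numeric array.
#' @return Array of the same shape with standardized channels.
#' @export
standardize_channels <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    out[, , ch] <- if (s < 1e-12) 0 else (v - m) / s
  }
  out
}

#' A small deterministic convolutional feature extractor
#'
#' A fixed-seed stack of valid 3x3 convolutions with ReLU activations,
#' interleaved with 2x2 mean-pooling layers. It satisfies the same
#' extractor contract as a pretrained backbone adapter (named layers, each
#' with a kernel size and stride) and is the tested reference extractor:
#' weights are drawn once from the given seed so feature maps are
#' bitwise-reproducible with no downloads.
#'
#' @param seed Integer seed for the weights.
#' @param channels Output channels of the successive conv layers.
#' @return Object of class `feature_extractor`: list with `id` and
#'   `layers` (each layer a list with `name`, `type` ("conv" or "pool"),
#'   `kernel`, `stride`, and for conv layers a `weights` array
#'   k x k x Cin x Cout).
#' @export
toy_extractor <- function(seed = 42L, channels = c(8L, 16L, 32L, 32L)) {
  with_seed(seed, {
    layers <- list()
    c_in <- 3L
    for (i in seq_along(channels)) {
      c_out <- channels[i]
      k <- 3L
      w <- array(stats::rnorm(k * k * c_in * c_out, sd = 1 / sqrt(k * k * c_in)),
                 c(k, k, c_in, c_out))
      layers[[length(layers) + 1L]] <- list(
        name = sprintf("conv%d", i), type = "conv",
        kernel = k, stride = 1L, weights = w
      )
      layers[[length(layers) + 1L]] <- list(
        name = sprintf("pool%d", i), type = "pool",
        kernel = 2L, stride = 2L
      )
      c_in <- c_out
    }
    structure(list(id = sprintf("toy-conv-%d", seed), layers = layers),
              class = "feature_extractor")
  })
}

#' An identity extractor (layer 0 returns the input pixels)
#'
#' @return A `feature_extractor` with no layers; only `layer_index = 0` is
#'   valid and yields the input image rearranged to channels-first.
#' @export
identity_extractor <- function() {
  structure(list(id = "identity", layers = list()), class = "feature_extractor")
}

conv_valid <- function(x, w, stride) {
  k <- dim(w)[1]
  c_in <- dim(w)[3]
  c_out <- dim(w)[4]
  h_out <- (dim(x)[1] - k) %/% stride + 1L
  w_out <- (dim(x)[2] - k) %/% stride + 1L
  if (h_out < 1L || w_out < 1L) stop("image too small for this layer", call. = FALSE)
  out <- array(0, c(h_out, w_out, c_out))
  for (a in seq_len(k)) {
    rows <- seq(a, by = stride, length.out = h_out)
    for (b in seq_len(k)) {
      cols <- seq(b, by = stride, length.out = w_out)
      xs <- x[rows, cols, , drop = FALSE]
      wm <- matrix(w[a, b, , ], nrow = c_in, ncol = c_out)
      out <- out + array(matrix(xs, ncol = c_in) %*% wm, c(h_out, w_out, c_out))
    }
  }
  out
}

pool_mean <- function(x, kernel, stride) {
  h_out <- (dim(x)[1] - kernel) %/% stride + 1L
  w_out <- (dim(x)[2] - kernel) %/% stride + 1L
  if (h_out < 1L || w_out < 1L) stop("image too small for this layer", call. = FALSE)
  out <- array(0, c(h_out, w_out, dim(x)[3]))
  for (a in seq_len(kernel)) {
    rows <- seq(a, by = stride, length.out = h_out)
    for (b in seq_len(kernel)) {
      cols <- seq(b, by = stride, length.out = w_out)
      out <- out + x[rows, cols, , drop = FALSE]
    }
  }
  out / (kernel^2)
}

#' Extract a feature map from an image at a given extractor layer
#'
#' Applies the extractor's layers fully convolutionally up to
#' `layer_index`, so images of any size are processed at native
#' resolution. `layer_index = 0` returns the input pixels rearranged to
#' channels-first (C = 3).
#'
#' @param image H x W x 3 numeric array (standardized upstream).
#' @param extractor A `feature_extractor`.
#' @param layer_index Integer in `0..length(extractor$layers)`.
#' @return Object of class `feature_map`: list with `values` (C x h x w
#'   array), `extractor_id`, `layer_index`.
#' @export
extract_features <- function(image, extractor, layer_index) {
  stopifnot(inherits(extractor, "feature_extractor"))
  n_layers <- length(extractor$layers)
  if (layer_index < 0L || layer_index > n_layers) {
    stop("layer_index must be in 0..", n_layers, call. = FALSE)
  }
  x <- image
  if (layer_index >= 1L) {
    for (l in seq_len(layer_index)) {
      layer <- extractor$layers[[l]]
      x <- switch(layer$type,
        conv = {
          z <- conv_valid(x, layer$weights, layer$stride)
          array(pmax(z, 0), dim(z))  # ReLU, keeping the array shape
        },
        pool = pool_mean(x, layer$kernel, layer$stride),
        stop("unknown layer type ", layer$type, call. = FALSE)
      )
    }
  }
  structure(
    list(
      values = aperm(x, c(3, 1, 2)),
      extractor_id = extractor$id,
      layer_index = as.integer(layer_index)
    ),
    class = "feature_map"
  )
}

#' Receptive-field geometry of an extractor layer
#'
#' @param extractor A `feature_extractor`.
#' @param layer_index Layer index (1-based).
#' @return List with `size` (input pixels covered by one output unit) and
#'   `stride` (input pixels between adjacent output units).
#' @export
receptive_field <- function(extractor, layer_index) {
  size <- 1
  stride <- 1
  for (l in seq_len(layer_index)) {
    layer <- extractor$layers[[l]]
    size <- size + (layer$kernel - 1) * stride
    stride <- stride * layer$stride
  }
  list(size = size, stride = stride)
}

#' Spatial mean pooling of a feature map
#'
#' Averages each channel over its full spatial extent, producing one
#' fixed-length vector per core regardless of image size.
#'
#' @param map A `feature_map`.
#' @return Numeric vector of length C.
#' @export
spatial_mean_pool <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  if (length(dim(v)) != 3L || prod(dim(v)[2:3]) == 0L) {
    stop("feature map has empty spatial extent", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("non-finite values in feature map", call. = FALSE)
  apply(v, 1, mean)
}

#' Average a patient's core feature vectors into one patient vector
#'
#' @param cores A list of numeric vectors (or a matrix with one core per
#'   row), all the same length.
#' @param label The patient's early-recurrence label.
#' @return Object of class `patient_feature`: list with `vector`, `label`,
#'   `n_cores`.
#' @export
aggregate_patient <- function(cores, label = NA) {
  if (is.matrix(cores)) cores <- asplit(cores, 1)
  if (length(cores) < 1L) stop("need at least one core", call. = FALSE)
  lens <- vapply(cores, length, 1L)
  if (length(unique(lens)) != 1L) stop("core vectors differ in length", call. = FALSE)
  v <- Reduce(`+`, lapply(cores, as.numeric)) / length(cores)
  structure(list(vector = v, label = label, n_cores = length(cores)),
            class = "patient_feature")
}

#' Patient-level feature matrix from per-core features
#'
#' Convenience wrapper: averages each patient's core vectors (via the same
#' arithmetic as [aggregate_patient()]) and returns a matrix keyed by
#' patient.
#'
#' @param cf A `core_features` object (or list with `x`, `patient_id`).
#' @return List with `x` (patients x C matrix, rownames = patient ids) and
#'   `patient_id`.
#' @export
patient_feature_matrix <- function(cf) {
  ids <- unique(cf$patient_id)
  x <- matrix(0, length(ids), ncol(cf$x), dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    rows <- cf$patient_id == ids[i]
    x[i, ] <- colMeans(cf$x[rows, , drop = FALSE])
  }
  list(x = x, patient_id = ids)
}

#' Within- and between-patient cosine similarity of core features
#'
#' Averages the cosine similarity over all pairs of cores from the same
#' patient (within) and all pairs from different patients (between).
#' Zero-norm vectors are excluded with a warning.
#'
#' @param cf A `core_features` object (or list with `x`, `patient_id`).
#' @return List with `within_mean`, `between_mean`, `n_within_pairs`,
#'   `n_between_pairs`.
#' @export
cosine_similarity_stats <- function(cf) {
  x <- cf$x
  pid <- cf$patient_id
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm < 1e-300
  if (any(zero)) {
    warning(sum(zero), " zero-norm core vectors excluded", call. = FALSE)
    x <- x[!zero, , drop = FALSE]
    pid <- pid[!zero]
    nrm <- nrm[!zero]
  }
  if (length(unique(pid)) < 2L) stop("need cores from >= 2 patients", call. = FALSE)
  u <- x / nrm
  s <- tcrossprod(u)
  same <- outer(pid, pid, `==`)
  upper <- upper.tri(s)
  within <- s[upper & same]
  between <- s[upper & !same]
  if (length(within) == 0L) stop("no patient has >= 2 cores", call. = FALSE)
  list(
    within_mean = mean(within),
    between_mean = mean(between),
    n_within_pairs = length(within),
    n_between_pairs = length(between)
  )
}

#' Select the feature-extraction layer by held-out grid search
#'
#' For each candidate layer, patient-level features are built (extract,
#' spatial-mean-pool, average cores per patient), the downstream
#' max-margin classifier is fit on a stratified `split_fraction` of
#' patients, and validation accuracy is measured on the remainder. Returns
#' the layer with the highest validation accuracy; ties break to the
#' lowest layer index. If a validation draw lacks one of the classes the
#' split is redrawn with the next seed (logged via message).
#'
#' @param images_by_patient Named list (patient id -> list of images), or
#'   `NULL` when `features_by_layer` is given.
#' @param labels Named logical vector of patient labels.
#' @param extractor A `feature_extractor` (ignored when
#'   `features_by_layer` is given).
#' @param candidate_layers Integer vector of layer indices (>= 2 of them,
#'   unless only one is supplied, which is returned directly).
#' @param split_fraction Fraction of patients used for training.
#' @param seed Integer seed for the split.
#' @param features_by_layer Optional list (one element per candidate
#'   layer) of patient x C feature matrices with patient ids as rownames;
#'   bypasses image extraction.
#' @param regularization Margin-classifier regularization.
#' @return The selected layer index (integer) with an `"accuracy"`
#'   attribute naming each candidate's validation accuracy.
#' @export
select_layer <- function(images_by_patient = NULL, labels, extractor = NULL,
                         candidate_layers, split_fraction = 0.9, seed = 1L,
                         features_by_layer = NULL, regularization = 1.0) {
  candidate_layers <- sort(as.integer(candidate_layers))
  if (length(candidate_layers) == 1L) {
    return(structure(candidate_layers, accuracy = stats::setNames(NA_real_, candidate_layers)))
  }
  if (is.null(features_by_layer)) {
    stopifnot(!is.null(images_by_patient), inherits(extractor, "feature_extractor"))
    features_by_layer <- lapply(candidate_layers, function(li) {
      mats <- t(vapply(names(images_by_patient), function(pid) {
        vecs <- lapply(images_by_patient[[pid]], function(img) {
          spatial_mean_pool(extract_features(standardize_channels(img), extractor, li))
        })
        aggregate_patient(vecs)$vector
      }, numeric(length(spatial_mean_pool(extract_features(
        standardize_channels(images_by_patient[[1]][[1]]), extractor, li
      ))))))
      mats
    })
  }
  ids <- rownames(features_by_layer[[1]])
  if (is.null(ids)) ids <- names(labels)
  y <- as.logical(labels[ids])
  n <- length(ids)

  acc <- rep(NA_real_, length(candidate_layers))
  try_seed <- seed
  for (attempt in 1:20) {
    split <- with_seed(substream_seed(try_seed, "layer-split"), {
      tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
        k <- max(1L, round(split_fraction * length(ix)))
        if (length(ix) == 1L) ix else sample(ix, k)
      }), use.names = FALSE)
      tr
    })
    val <- setdiff(seq_len(n), split)
    if (length(val) >= 2L && length(unique(y[val])) == 2L &&
        length(unique(y[split])) == 2L) {
      for (j in seq_along(candidate_layers)) {
        xm <- features_by_layer[[j]]
        model <- margin_fit(xm[split, , drop = FALSE], y[split],
                            regularization = regularization)
        pred <- margin_predict(model, xm[val, , drop = FALSE])
        acc[j] <- mean(pred$label == y[val])
      }
      break
    }
    message("degenerate validation split; redrawing with next seed")
    try_seed <- try_seed + 1L
  }
  if (anyNA(acc)) stop("could not draw a non-degenerate validation split", call. = FALSE)
  best <- candidate_layers[which.max(acc)]  # which.max breaks ties low
  structure(best, accuracy = stats::setNames(acc, candidate_layers))
}

#' Read a core image from a PNG or TIFF file
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_core_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is needed to read TIFF images", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
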