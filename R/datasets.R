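#' Generate the binary-patch toy dataset
#'
#' Builds four binary `image_side x image_side` images, each its own class,
#' split into two tasks (images 0,1 then images 2,3). Interference between
#' tasks is controlled by a single knob: each task-1 image shares exactly
#' `overlap` on-pixels with its paired task-2 image (0 with 2, 1 with 3);
#' all other on-pixel sets are mutually disjoint. Every image has exactly
#' `n_on_pixels` on-pixels.
#'
#' @param overlap Number of on-pixels shared between paired cross-task
#'   images, in `[0, n_on_pixels]`.
#' @param n_on_pixels On-pixels per image.
#' @param image_side Side of the square image (default 10, i.e. 100 pixels).
#' @param seed Optional integer seed.
#' @return An object of class `patches`: list with `x` (4 x d binary matrix,
#'   rows flattened row-major), `y` (labels 0:3), `tasks` (class subsets),
#'   `categories` (per-pixel factor: `unique_t1`, `unique_t2`, `overlap`,
#'   `off`), and the generating parameters.
#' @export
generate_patches <- function(overlap = 0L, n_on_pixels = 20L,
                             image_side = 10L, seed = NULL) {
  n_on_pixels <- as.integer(n_on_pixels)
  overlap <- as.integer(overlap)
  d <- as.integer(image_side)^2
  if (overlap < 0L || overlap > n_on_pixels)
    stop("overlap must lie in [0, n_on_pixels]")
  need <- 4L * n_on_pixels - 2L * overlap
  if (need > d)
    stop("infeasible patch specification: 4*n_on_pixels - 2*overlap = ",
         need, " exceeds ", d, " pixels")
  if (!is.null(seed)) set.seed(seed)
  pool <- sample.int(d, need)
  u <- n_on_pixels - overlap
  take <- function(n) {
    if (n == 0L) return(integer(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  ov02 <- take(overlap); ov13 <- take(overlap)
  u0 <- take(u); u1 <- take(u); u2 <- take(u); u3 <- take(u)
  on_sets <- list(c(u0, ov02), c(u1, ov13), c(u2, ov02), c(u3, ov13))
  x <- matrix(0, nrow = 4L, ncol = d)
  for (i in 1:4) x[i, on_sets[[i]]] <- 1
  categories <- rep("off", d)
  categories[c(u0, u1)] <- "unique_t1"
  categories[c(u2, u3)] <- "unique_t2"
  categories[c(ov02, ov13)] <- "overlap"
  structure(list(x = x, y = 0:3, tasks = list(0:1, 2:3),
                 on_sets = on_sets, categories = categories,
                 overlap = overlap, n_on_pixels = n_on_pixels,
                 image_side = as.integer(image_side)),
            class = "patches")
}

## ---- IDX (MNIST-dialect) container -------------------------------------

idx_type_codes <- c("0x08" = 1L, "0x09" = 1L, "0x0b" = 2L,
                    "0x0c" = 4L, "0x0d" = 4L, "0x0e" = 8L)

#' Read an IDX file
#'
#' Parses the MNIST-dialect IDX container: two zero bytes, a type code, a
#' dimension count, big-endian 32-bit dimension sizes, then the payload.
#' Only the unsigned-byte payload type (0x08) is supported, which covers the
#' MNIST/Fashion-MNIST image and label files.
#'
#' @param path Path to the IDX file.
#' @return For a 1-d file, an integer vector (labels). For an n-d file, a
#'   numeric matrix with one flattened row-major item per row and pixel
#'   values divided by 255 into `[0, 1]`.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L)
    stop("bad IDX magic number at offset 0 in ", path)
  if (magic[3] != 0x08L)
    stop("unsupported IDX payload type 0x", sprintf("%02x", magic[3]),
         " at offset 2 (only uint8 is supported)")
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim) stop("truncated IDX dimension header in ", path)
  n_items <- prod(dims)
  payload <- readBin(con, "integer", n = n_items, size = 1L, signed = FALSE)
  if (length(payload) < n_items)
    stop("truncated IDX payload in ", path, ": expected ", n_items,
         " bytes after offset ", 4L + 4L * ndim, ", got ", length(payload))
  if (ndim == 1L) return(as.integer(payload))
  per_item <- prod(dims[-1L])
  # payload is stored item-major, each item row-major
  matrix(payload / 255, nrow = dims[1L], ncol = per_item, byrow = TRUE)
}

#' Write an IDX file (uint8 payload)
#'
#' Counterpart of [read_idx()], used to build small test fixtures and to
#' export datasets. Images are expected in `[0, 1]` and are rescaled to
#' bytes; labels are written as a 1-d uint8 file.
#'
#' @param data Matrix (one item per row, written with dims `n x side x side`
#'   when `image_side` is given, else `n x d`) or an integer vector.
#' @param path Output path.
#' @param image_side Optional side length to write a 3-d image file.
#' @export
write_idx <- function(data, path, image_side = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(data)) {
    vals <- as.integer(round(t(data) * 255))
    dims <- if (is.null(image_side)) dim(data)
            else c(nrow(data), image_side, image_side)
  } else {
    vals <- as.integer(data)
    dims <- length(data)
  }
  if (any(vals < 0L | vals > 255L)) stop("values do not fit in uint8")
  writeBin(as.raw(c(0L, 0L, 0x08L, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Read a paired IDX image/label dataset
#'
#' @param image_path,label_path Paths to the image and label IDX files.
#' @return List with `x` (n x d matrix in `[0, 1]`) and `y` (integer labels).
#' @export
read_idx_dataset <- function(image_path, label_path) {
  x <- read_idx(image_path)
  y <- read_idx(label_path)
  if (!is.matrix(x)) stop(image_path, " is not an image file")
  if (nrow(x) != length(y)) stop("label/image count mismatch: ",
                                 nrow(x), " images vs ", length(y), " labels")
  list(x = x, y = as.integer(y))
}

#' Read a generic feature-vector dataset from CSV
#'
#' Accepts externally produced embeddings (header `label, f0..fd`).
#'
#' @param path CSV path.
#' @return List with `x` (numeric matrix) and `y` (integer labels).
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("feature CSV needs a 'label' column")
  y <- as.integer(df$label)
  x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  list(x = x, y = y)
}

## ---- Task streams -------------------------------------------------------

#' Build a class-incremental or multi-modal task stream
#'
#' Splits a labelled dataset into an ordered sequence of tasks sharing one
#' global output head. The incremental protocol groups consecutive class
#' labels into fixed subsets of `classes_per_task` (e.g. 10 classes into
#' five tasks 0/1, 2/3, ...); the task *order* may be permuted, the class
#' pairing never is. The multimodal protocol takes two whole datasets as the
#' two tasks, mapped onto the same output units. Test data always cover all
#' classes of the full protocol.
#'
#' @param train,test Lists with `x`, `y` (for `"multimodal"`: lists of two
#'   such datasets). For `"patches"`, pass a [generate_patches()] object as
#'   `train` and leave `test` `NULL` (the four images are both splits).
#' @param protocol One of `"incremental"`, `"multimodal"`, `"patches"`.
#' @param classes_per_task Classes per task for the incremental protocol.
#' @param order Optional explicit permutation of task indices.
#' @param order_seed Optional seed to draw a random task order.
#' @return An object of class `task_stream`: list with `tasks` (each a list
#'   `task_id`, `classes`, `x`, `y`), `test` (full-coverage test split),
#'   `task_classes` (per-task class subsets, in stream order) and
#'   `n_classes`.
#' @export
build_task_stream <- function(train, test = NULL,
                              protocol = c("incremental", "multimodal",
                                           "patches"),
                              classes_per_task = 2L, order = NULL,
                              order_seed = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "patches") {
    stopifnot(inherits(train, "patches"))
    tasks <- lapply(1:2, function(i) {
      cls <- train$tasks[[i]]
      sel <- train$y %in% cls
      list(task_id = i, classes = cls,
           x = train$x[sel, , drop = FALSE], y = train$y[sel])
    })
    out <- list(tasks = tasks, test = list(x = train$x, y = train$y),
                task_classes = train$tasks, n_classes = 4L,
                protocol = protocol)
    class(out) <- "task_stream"
    return(out)
  }
  if (protocol == "multimodal") {
    stopifnot(length(train) == 2L, length(test) == 2L)
    k1 <- length(unique(train[[1]]$y)); k2 <- length(unique(train[[2]]$y))
    if (k1 != k2) stop("multimodal datasets must share the output head size")
    tasks <- lapply(1:2, function(i)
      list(task_id = i, classes = sort(unique(train[[i]]$y)),
           x = as.matrix(train[[i]]$x), y = as.integer(train[[i]]$y)))
    test_all <- list(x = rbind(as.matrix(test[[1]]$x), as.matrix(test[[2]]$x)),
                     y = c(as.integer(test[[1]]$y), as.integer(test[[2]]$y)))
    # per-task test membership tracked by row block, not class label, since
    # both modalities reuse the same labels
    test_task <- rep(1:2, c(length(test[[1]]$y), length(test[[2]]$y)))
    out <- list(tasks = tasks, test = test_all,
                task_classes = lapply(tasks, `[[`, "classes"),
                test_task = test_task, n_classes = k1, protocol = protocol)
    class(out) <- "task_stream"
    return(out)
  }
  ## incremental
  y <- as.integer(train$y)
  classes <- sort(unique(y))
  if (!identical(classes, seq_along(classes) - 1L))
    stop("class labels must be contiguous from 0")
  if (length(classes) %% classes_per_task != 0L)
    stop("number of classes (", length(classes),
         ") is not divisible by classes_per_task (", classes_per_task, ")")
  groups <- split(classes, (classes %/% classes_per_task))
  n_tasks <- length(groups)
  if (is.null(order)) {
    if (!is.null(order_seed)) set.seed(order_seed)
    order <- if (is.null(order_seed)) seq_len(n_tasks) else sample.int(n_tasks)
  }
  stopifnot(identical(sort(as.integer(order)), seq_len(n_tasks)))
  x <- as.matrix(train$x)
  tasks <- lapply(seq_len(n_tasks), function(i) {
    cls <- groups[[order[i]]]
    sel <- y %in% cls
    list(task_id = i, classes = cls, x = x[sel, , drop = FALSE], y = y[sel])
  })
  out <- list(tasks = tasks,
              test = list(x = as.matrix(test$x), y = as.integer(test$y)),
              task_classes = lapply(tasks, `[[`, "classes"),
              n_classes = length(classes), protocol = protocol)
  class(out) <- "task_stream"
  out
}

## ---- Input statistics ---------------------------------------------------

#' Running mean-intensity statistics of training inputs
#'
#' The only trace of past tasks that the sleep phase needs: the per-element
#' mean intensity over every training input observed so far. Stored as an
#' exact running mean, so its size never grows with the number of tasks.
#'
#' @param n_inputs Input dimensionality.
#' @return An object of class `input_stats` with fields `mean_intensity`
#'   (numeric vector) and `n_samples_seen`.
#' @export
new_input_statistics <- function(n_inputs) {
  structure(list(mean_intensity = numeric(n_inputs), n_samples_seen = 0L),
            class = "input_stats")
}

#' Update input statistics with a batch of inputs
#'
#' @param stats An `input_stats` object.
#' @param x Matrix of inputs in `[0, 1]`, one sample per row.
#' @return The updated `input_stats`.
#' @export
update_input_statistics <- function(stats, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean_intensity))
    stop("input dimension mismatch: batch has ", ncol(x),
         " columns, statistics track ", length(stats$mean_intensity))
  n0 <- stats$n_samples_seen
  m <- nrow(x)
  if (m == 0L) return(stats)
  stats$mean_intensity <- (stats$mean_intensity * n0 + colSums(x)) / (n0 + m)
  stats$n_samples_seen <- n0 + m
  stats
}

## ---- Synthetic image fixture -------------------------------------------

#' Generate a synthetic MNIST-like image dataset
#'
#' Each class has a binary prototype of `n_on_pixels` bright pixels on a
#' square canvas; cross-task interference mirrors the toy patches: class `c`
#' of task 1 shares `overlap` prototype pixels with its paired class in task
#' 2 (classes are paired `c` with `c + n_classes/2`), and all other
#' prototype pixels are disjoint. A sample is drawn pixel-wise Bernoulli
#' from the prototype and each pixel is then flipped with probability
#' `noise`. Class-conditional mean intensities therefore differ across
#' classes while the global mean-intensity vector (which drives sleep noise)
#' is well defined.
#'
#' @param n_classes Even number of classes (two tasks of `n_classes/2`).
#' @param samples_per_class Samples generated per class.
#' @param n_on_pixels Prototype on-pixels per class.
#' @param overlap Prototype pixels shared between paired cross-task classes.
#' @param noise Pixel flip probability in `[0, 1)`.
#' @param image_side Canvas side length.
#' @param seed Optional integer seed.
#' @return List with `x` (n x d binary matrix), `y` (0-based labels),
#'   `prototypes` (class x d probability matrix) and the parameters.
#' @export
generate_synthetic_images <- function(n_classes = 4L, samples_per_class = 100L,
                                      n_on_pixels = 20L, overlap = 14L,
                                      noise = 0.05, image_side = 10L,
                                      seed = NULL) {
  if (noise < 0 || noise >= 1) stop("noise must lie in [0, 1)")
  if (n_classes %% 2L != 0L) stop("n_classes must be even (two tasks)")
  d <- as.integer(image_side)^2
  half <- n_classes %/% 2L
  need <- half * (2L * n_on_pixels - overlap)
  if (overlap < 0L || overlap > n_on_pixels || need > d)
    stop("infeasible prototype specification")
  if (!is.null(seed)) set.seed(seed)
  pool <- sample.int(d, need)
  take <- function(n) {
    if (n == 0L) return(integer(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  prototypes <- matrix(0, nrow = n_classes, ncol = d)
  for (c1 in seq_len(half)) {
    ov <- take(overlap)
    prototypes[c1, c(ov, take(n_on_pixels - overlap))] <- 1
    prototypes[c1 + half, c(ov, take(n_on_pixels - overlap))] <- 1
  }
  n <- n_classes * samples_per_class
  y <- rep(seq_len(n_classes) - 1L, each = samples_per_class)
  p <- prototypes[y + 1L, , drop = FALSE]
  draw <- matrix(stats::runif(n * d) < p, nrow = n) * 1
  flip <- matrix(stats::runif(n * d) < noise, nrow = n)
  x <- ifelse(flip, 1 - draw, draw)
  list(x = x, y = y, prototypes = prototypes, n_classes = n_classes,
       image_side = as.integer(image_side), noise = noise,
       n_on_pixels = as.integer(n_on_pixels), overlap = as.integer(overlap))
}

#' Train/test fixture of synthetic images ready for a task stream
#'
#' Convenience wrapper drawing disjoint train and test sets from the same
#' prototypes.
#'
#' @param n_train,n_test Samples per class in each split.
#' @param ... Passed to [generate_synthetic_images()].
#' @param seed Integer seed (prototypes and both splits derive from it).
#' @return List with `train`, `test` (each `x`, `y`) and `prototypes`.
#' @export
synthetic_fixture <- function(n_train = 100L, n_test = 50L, seed = 1L, ...) {
  full <- generate_synthetic_images(samples_per_class = n_train + n_test,
                                    seed = seed, ...)
  n_classes <- full$n_classes
  per <- n_train + n_test
  train_idx <- unlist(lapply(seq_len(n_classes) - 1L, function(k)
    which(full$y == k)[seq_len(n_train)]))
  test_idx <- setdiff(seq_along(full$y), train_idx)
  list(train = list(x = full$x[train_idx, , drop = FALSE],
                    y = full$y[train_idx]),
       test = list(x = full$x[test_idx, , drop = FALSE],
                   y = full$y[test_idx]),
       prototypes = full$prototypes, n_classes = n_classes)
}
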