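## 8-connected component labeling (BFS flood fill). EBImage's labeling is
## 4-connected, which splits rods touching only diagonally.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- start
    lab[start] <- nextlab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab
}

#' Segment bright objects in a 2-D image
#'
#' Background subtraction (median of the image), global Otsu threshold,
#' 8-connected component labeling and a minimum-area filter — the
#' object-detection step used to identify single bacteria before feature
#' extraction.
#'
#' @param image Numeric matrix.
#' @param min_area Minimum object area in pixels (default 20).
#' @return List of `segmented_object`s (fields `id`, `pixels` — linear
#'   indices into the image —, `centroid` `(row, col)`, `area`), with the
#'   integer label matrix in attribute `"labels"`. An image without
#'   foreground yields an empty list.
#' @export
segment <- function(image, min_area = 20) {
  stopifnot(is.matrix(image), !anyNA(image))
  x <- image - stats::median(image)
  x[x < 0] <- 0
  if (max(x) <= 0) return(structure(list(), labels = matrix(0L, nrow(image), ncol(image))))
  xn <- x / max(x)
  th <- EBImage::otsu(EBImage::Image(xn))
  mask <- xn > th
  lab <- label_components8(mask)
  keep <- 0L
  out <- list()
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (l in seq_len(max(lab))) {
    px <- which(lab == l)
    if (length(px) < min_area) next
    keep <- keep + 1L
    relab[px] <- keep
    rc <- arrayInd(px, dim(image))
    out[[keep]] <- structure(
      list(id = keep, pixels = px,
           centroid = c(row = mean(rc[, 1]), col = mean(rc[, 2])),
           area = length(px)),
      class = "segmented_object")
  }
  structure(out, labels = relab)
}

## per-object mean intensity trace across frames
object_traces <- function(stack, objects) {
  nf <- dim(stack)[1]
  t(vapply(objects, function(ob) {
    vapply(seq_len(nf), function(f) mean(stack[f, , ][ob$pixels]), 0)
  }, numeric(nf)))
}

#' Four-dose unmixing features plus photobleaching loss
#'
#' Implements the intra-pixel dose-modulation feature extraction: frames
#' are grouped in consecutive fours, the intensity of every 4th frame
#' normalizes the three preceding ones, and the normalized triplet is
#' averaged across groups, giving three kinetic features per object. The
#' fluorescence loss across the time-lapse — the drop in mean raw
#' normalizer intensity between the first three and last three groups —
#' is the fourth feature; it is divided by the early mean so the feature
#' is dimensionless and gain-invariant (an absolute-difference mode is
#' available).
#'
#' @param stack Numeric array `frame x row x col`; the frame count must be
#'   divisible by `frames_per_group`.
#' @param objects List of `segmented_object`s from [segment()].
#' @param frames_per_group Frames per normalization group (default 4).
#' @param loss_mode `"normalized"` (default) or `"absolute"`.
#' @return Data frame with `object`, `f1`, `f2`, `f3`, `loss`, `valid`.
#'   Objects with a non-positive normalizer intensity are flagged invalid
#'   (with a warning) and carry NA features.
#' @export
build_unmix_features <- function(stack, objects, frames_per_group = 4,
                                 loss_mode = c("normalized", "absolute")) {
  loss_mode <- match.arg(loss_mode)
  nf <- dim(stack)[1]
  if (nf %% frames_per_group != 0)
    stop("frame count (", nf, ") not divisible by ", frames_per_group)
  ngroup <- nf %/% frames_per_group
  if (ngroup < 2) stop("need >= 2 normalization groups for the bleaching feature")
  traces <- object_traces(stack, objects)
  res <- lapply(seq_along(objects), function(i) {
    m <- traces[i, ]
    norm_idx <- seq_len(ngroup) * frames_per_group
    normalizers <- m[norm_idx]
    if (any(normalizers <= 0)) {
      warning("object ", objects[[i]]$id,
              " has a non-positive normalizer intensity; excluded")
      return(data.frame(object = objects[[i]]$id, f1 = NA_real_,
                        f2 = NA_real_, f3 = NA_real_, loss = NA_real_,
                        valid = FALSE))
    }
    feats <- vapply(seq_len(frames_per_group - 1), function(k) {
      mean(m[(seq_len(ngroup) - 1) * frames_per_group + k] / normalizers)
    }, 0)
    early <- mean(normalizers[1:3])
    late <- mean(normalizers[(ngroup - 2):ngroup])
    loss <- if (loss_mode == "normalized") (early - late) / early
            else early - late
    data.frame(object = objects[[i]]$id, f1 = feats[1], f2 = feats[2],
               f3 = feats[3], loss = loss, valid = TRUE)
  })
  do.call(rbind, res)
}

#' Train per-class Gaussians in the 4-D unmixing space
#'
#' Fits one Gaussian per labeled class (mean and, by default, diagonal
#' covariance — the per-protein "mu and sigma") with mixing weights given
#' by class frequencies.
#'
#' @param features Data frame with columns `f1`, `f2`, `f3`, `loss`.
#' @param labels Class label per row of `features`.
#' @param covariance `"diagonal"` (default) or `"full"`.
#' @param min_per_class Minimum objects per class (default 10).
#' @return A `class_model`: per-class `mean`, `cov`, `weight`.
#' @export
train_classes <- function(features, labels,
                          covariance = c("diagonal", "full"),
                          min_per_class = 10) {
  covariance <- match.arg(covariance)
  X <- as.matrix(features[, c("f1", "f2", "f3", "loss")])
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    if (length(classes) == 0) stop("no labeled objects")
  }
  tab <- table(labels)
  if (any(tab < min_per_class))
    stop("classes with fewer than ", min_per_class, " objects: ",
         paste(names(tab)[tab < min_per_class], collapse = ", "))
  comp <- lapply(classes, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    if (covariance == "diagonal") {
      v <- apply(Xi, 2, stats::var)
      if (any(v < 1e-6)) {
        warning("variance floor applied for class ", cl)
        v <- pmax(v, 1e-6)
      }
      S <- diag(v, ncol(X))
    } else {
      S <- stats::cov(Xi)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-6) {
        warning("covariance regularized for class ", cl)
        S <- S + diag(1e-6 - min(ev, 0), ncol(X))
      }
    }
    list(mean = mu, cov = S, weight = unname(tab[cl]) / length(labels))
  })
  names(comp) <- classes
  structure(list(components = comp, classes = classes,
                 covariance = covariance),
            class = "class_model")
}

log_gauss <- function(X, mu, S) {
  d <- ncol(X)
  L <- chol(S)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - d / 2 * log(2 * pi)
}

#' Classify objects with a trained Gaussian mixture
#'
#' Maximum-posterior classification of unmixing features under the
#' trained per-class Gaussians, as in the re-analysis of the full dataset
#' with the fitted mixture model.
#'
#' @param features Data frame with columns `f1`, `f2`, `f3`, `loss`.
#' @param model A `class_model` from [train_classes()].
#' @return Data frame with `label` (predicted class) and one posterior
#'   column per class (rows sum to 1).
#' @export
classify <- function(features, model) {
  X <- as.matrix(features[, c("f1", "f2", "f3", "loss")])
  if (ncol(X) != length(model$components[[1]]$mean))
    stop("feature dimensionality does not match the model")
  lp <- vapply(model$classes, function(cl) {
    cm <- model$components[[cl]]
    log(cm$weight) + log_gauss(X, cm$mean, cm$cov)
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  out <- data.frame(label = model$classes[max.col(post)], post,
                    check.names = FALSE)
  out
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true,predicted Label vectors of equal length.
#' @return Integer matrix `[true class, predicted class]` over the union
#'   of observed labels; row sums equal per-class object counts.
#' @export
confusion <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  lev <- sort(unique(c(as.character(true), as.character(predicted))))
  m <- table(factor(true, lev), factor(predicted, lev))
  m <- unclass(m)
  names(dimnames(m)) <- c("true", "predicted")
  m
}

#' Overall accuracy of a confusion matrix
#' @param cm Matrix from [confusion()].
#' @export
accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Off-switching-rate classification of a decay time-lapse
#'
#' For a time-lapse in which each frame's readout progressively
#' off-switches the labels, fits a mono-exponential decay to each
#' object's per-frame intensity trace and classifies objects into two
#' populations by thresholding the fitted rate at the midpoint of a 1-D
#' two-component Gaussian fit of the rates. Also reports each object's
#' fluorescence loss, `1 - mean(last 3 frames)/mean(first 3 frames)`.
#'
#' @param stack Numeric array `frame x row x col` (e.g. 50 frames).
#' @param objects List of `segmented_object`s.
#' @param seed Seed for the mixture initialization.
#' @return Data frame `object`, `rate` (1/frame), `loss`, `label`
#'   (`"slow"`/`"fast"`, NA for failed fits), with the rate threshold in
#'   attribute `"threshold"` and `attr(, "degenerate") = TRUE` when the
#'   two rate components are indistinguishable.
#' @export
offswitch_classify <- function(stack, objects, seed = 1234) {
  traces <- object_traces(stack, objects)
  nf <- ncol(traces)
  fits <- lapply(seq_along(objects), function(i) {
    y <- traces[i, ]
    f <- tryCatch(fit_exponential(seq_len(nf), y, "decay"),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("decay fit failed for object ", objects[[i]]$id, "; excluded")
      return(c(rate = NA_real_, loss = NA_real_))
    }
    c(rate = 1 / unname(f$parameters["tau"]),
      loss = 1 - mean(y[(nf - 2):nf]) / mean(y[1:3]))
  })
  rates <- vapply(fits, `[`, 0, "rate")
  losses <- vapply(fits, `[`, 0, "loss")
  ok <- !is.na(rates)
  degenerate <- FALSE
  thr <- NA_real_
  label <- rep(NA_character_, length(rates))
  if (sum(ok) >= 4) {
    set.seed(seed)
    mix <- gmm1d_2comp(rates[ok])
    mu <- sort(mix$mean)
    ## bimodality index (Ashman's D); a split of a single tight mode
    ## scores ~1-2, genuinely distinct rate populations score >> 4
    D <- diff(mu) / sqrt(mean(mix$var))
    if (!is.finite(D) || D < 4 || min(mix$weight) < 0.1) degenerate <- TRUE
    thr <- mean(mu)
    label[ok] <- ifelse(rates[ok] < thr, "slow", "fast")
  } else degenerate <- TRUE
  if (degenerate && sum(ok) > 0 && is.na(thr)) {
    thr <- stats::median(rates[ok])
    label[ok] <- ifelse(rates[ok] <= thr, "slow", "fast")
  }
  structure(data.frame(object = vapply(objects, `[[`, 0L, "id"),
                       rate = rates, loss = losses, label = label),
            threshold = thr, degenerate = degenerate)
}

## 1-D two-component Gaussian mixture by EM, initialized at the lower and
## upper quartiles.
gmm1d_2comp <- function(x, max_iter = 200, tol = 1e-10) {
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  v <- rep(max(stats::var(x) / 4, 1e-12), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    if (any(w < 1e-9)) break
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    v <- pmax(c(sum(r * (x - mu[1])^2) / sum(r),
                sum((1 - r) * (x - mu[2])^2) / sum(1 - r)), 1e-12)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mean = mu, var = v, weight = w)
}

#' Ratiometric slow/fast image
#'
#' Divides a background-subtracted slow-activation image by the
#' corresponding fast-activation image on the Otsu foreground mask of the
#' fast image; background pixels are NA.
#'
#' @param slow_img,fast_img Numeric matrices of identical shape.
#' @return List with `ratio` (matrix, NA outside the mask), `values`
#'   (masked pixel ratios) and `mask`.
#' @export
ratiometric_image <- function(slow_img, fast_img) {
  stopifnot(is.matrix(slow_img), all(dim(slow_img) == dim(fast_img)))
  s <- slow_img - stats::median(slow_img); s[s < 0] <- 0
  f <- fast_img - stats::median(fast_img); f[f < 0] <- 0
  if (max(f) <= 0) stop("empty foreground mask in the fast image")
  fn <- f / max(f)
  mask <- fn > EBImage::otsu(EBImage::Image(fn))
  if (!any(mask)) stop("empty foreground mask in the fast image")
  ratio <- matrix(NA_real_, nrow(s), ncol(s))
  ratio[mask] <- s[mask] / f[mask]
  list(ratio = ratio, values = ratio[mask], mask = mask)
}
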