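#' Smooth multiplicative bias-field correction
#'
#' Corrects slowly varying intensity inhomogeneity with a low-order
#' polynomial model of the log-intensity. A bright-tissue band (foreground
#' voxels above the 60th foreground percentile, dominated by the most
#' intense tissue) anchors the fit: within one tissue, spatial variation of
#' the log-intensity is bias plus noise, so a polynomial fit to those
#' voxels recovers the field without absorbing anatomy. The fit is
#' iterated (re-selecting the band on the corrected image), the field is
#' normalized so the mean foreground intensity is preserved, and the image
#' is divided by it. The field is strictly positive everywhere.
#'
#' @param image [image_volume()] with non-negative intensities.
#' @param order Polynomial order of the field model (default 2).
#' @param iterations Fit iterations (default 2).
#' @return `list(image = corrected image_volume, field = image_volume)`.
#' @export
correct_bias <- function(image, order = 2, iterations = 2) {
  assert_that(any(image$data > 0), "cannot bias-correct an all-zero image")
  d <- dim(image$data)
  vals <- as.numeric(image$data)
  fg_thresh <- 0.25 * stats::quantile(vals[vals > 0], 0.99)
  fg <- vals > fg_thresh
  # coordinates normalized to the foreground bounding box (the head), so
  # the polynomial is evaluated near its fitted support and extrapolation
  # to the image corners stays mild
  ijk <- voxel_grid(image)
  lo <- apply(ijk[fg, , drop = FALSE], 2, min)
  hi <- apply(ijk[fg, , drop = FALSE], 2, max)
  nc <- sweep(sweep(ijk, 2, (lo + hi) / 2), 2, pmax((hi - lo) / 2, 1), "/")
  # constant extrapolation beyond the head: clamp to the fitted domain
  nc <- pmin(pmax(nc, -1), 1)
  basis <- cbind(1, nc)
  if (order >= 2) {
    basis <- cbind(basis, nc[, 1]^2, nc[, 2]^2, nc[, 3]^2,
                   nc[, 1] * nc[, 2], nc[, 1] * nc[, 3], nc[, 2] * nc[, 3])
  }
  cur <- vals
  logfield <- rep(0, length(vals))
  for (it in seq_len(iterations)) {
    # band of the brightest tissue: within +/-15% of the 90th foreground
    # percentile, so a single tissue class anchors the fit and anatomy is
    # not absorbed into the field
    m <- stats::quantile(cur[fg], 0.90)
    band <- fg & abs(cur - m) < 0.15 * m
    if (sum(band) < 4 * ncol(basis)) break
    fit <- stats::lsfit(basis[band, -1, drop = FALSE], log(cur[band]),
                        intercept = TRUE)
    pred <- as.numeric(basis %*% fit$coefficients)
    pred <- pred - mean(pred[band])  # field relative to the band mean
    logfield <- logfield + pred
    # the polynomial extrapolates outside the band's support; keep the
    # field within a plausible range
    logfield <- pmin(pmax(logfield, -0.7), 0.7)
    cur <- vals / exp(logfield)
  }
  field <- exp(logfield)
  corrected <- vals / field
  # preserve mean foreground intensity exactly
  scale <- mean(vals[fg]) / mean(corrected[fg])
  corrected <- corrected * scale
  field <- field / scale
  out <- image
  out$data <- array(corrected, dim = d)
  fvol <- image
  fvol$data <- array(field, dim = d)
  list(image = out, field = fvol)
}

#' Tissue probability map from registered atlases
#'
#' Registers every atlas to the subject (affine then coarse non-rigid,
#' both by mutual information), resamples the atlas label images onto the
#' subject grid with nearest-neighbour interpolation, and averages the
#' votes: the per-class probability at a voxel is the fraction of atlases
#' voting that class, so every probability is a multiple of `1/n` and the
#' four class probabilities sum to 1 at every voxel. The per-atlas
#' transformed intracranial and cerebrum masks are returned alongside for
#' majority-vote skull masking. An atlas whose registration errors out is
#' dropped with a warning; if all are dropped, the call fails.
#'
#' @param atlases An `atlas_set` (see [generate_atlas_set()]).
#' @param subject Subject [image_volume()] (bias-corrected).
#' @param config A [reg_config()].
#' @param nonrigid Run the non-rigid refinement after the affine stage.
#' @return An object of class `probability_map`: per-class arrays
#'   `background`, `csf`, `gm`, `wm`, the subject geometry, `n_atlases`,
#'   plus `icv_masks`, `cerebrum_masks` and `transforms` lists.
#' @export
build_probability_map <- function(atlases, subject, config = reg_config(),
                                  nonrigid = TRUE) {
  assert_that(inherits(atlases, "atlas_set") && atlases$count >= 1,
              "need an atlas_set with >= 1 atlas")
  d <- dim(subject$data)
  votes <- array(0, dim = c(d, 4))
  icv_masks <- list(); cerebrum_masks <- list(); transforms <- list()
  used <- 0
  for (i in seq_len(atlases$count)) {
    a <- atlases$atlases[[i]]
    res <- tryCatch({
      areg <- affine_register(a$intensity, subject, config)
      tf <- areg$transform
      if (nonrigid) {
        nreg <- nonrigid_register(a$intensity, subject, tf, config)
        tf <- nreg$field
      }
      labs <- apply_transform(a$labels, tf, subject, interpolation = "nearest",
                              fill = 0)
      list(tf = tf,
           labs = labs,
           icv = apply_transform(a$intracranial, tf, subject,
                                 interpolation = "nearest", fill = 0),
           cer = apply_transform(a$cerebrum, tf, subject,
                                 interpolation = "nearest", fill = 0))
    }, error = function(e) {
      warning(sprintf("atlas %d dropped: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    used <- used + 1
    for (cl in 0:3) {
      votes[, , , cl + 1] <- votes[, , , cl + 1] + (res$labs$data == cl)
    }
    icv_masks[[used]] <- res$icv
    cerebrum_masks[[used]] <- res$cer
    transforms[[used]] <- res$tf
  }
  assert_that(used >= 1, "all atlas registrations failed")
  structure(list(background = votes[, , , 1] / used,
                 csf = votes[, , , 2] / used,
                 gm = votes[, , , 3] / used,
                 wm = votes[, , , 4] / used,
                 spacing = subject$spacing, origin = subject$origin,
                 direction = subject$direction, n_atlases = used,
                 icv_masks = icv_masks, cerebrum_masks = cerebrum_masks,
                 transforms = transforms),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s voxels from %d atlases\n",
              paste(dim(x$csf), collapse = "x"), x$n_atlases))
  invisible(x)
}

#' Majority-vote mask fusion
#'
#' Fuses transformed binary masks into one: a voxel is included when the
#' fraction of masks voting for it is at least `threshold` (default 0.8 —
#' with six atlases, 5 of 6 votes include a voxel, 4 of 6 do not).
#'
#' @param masks List of binary [image_volume()]s on one grid.
#' @param threshold Vote fraction needed for inclusion (inclusive).
#' @return A binary [image_volume()].
#' @export
majority_mask <- function(masks, threshold = 0.8) {
  assert_that(length(masks) >= 1, "need at least one mask")
  votes <- Reduce(`+`, lapply(masks, function(m) m$data != 0))
  g <- masks[[1]]
  g$data <- array(as.numeric(votes / length(masks) >= threshold),
                  dim = dim(g$data))
  g
}

#' Extract high-confidence training samples for the kNN classifier
#'
#' Collects, for each tissue class, the voxels whose atlas probability
#' reaches `prob_threshold` (default 1.0: unanimous atlas agreement), and
#' subsamples them uniformly (seeded) to at most `max_per_class`. Features
#' are the (bias-corrected) intensities at those voxels; multi-channel
#' input contributes one feature per channel. If a class has fewer than
#' `k` candidates the threshold is lowered stepwise by `1/n_atlases` with
#' a warning; if it still cannot supply `k` samples, the error names the
#' class.
#'
#' @param image [image_volume()] or list of channel volumes on one grid.
#' @param pmap A `probability_map`.
#' @param prob_threshold Minimum class probability for a candidate voxel.
#' @param max_per_class Cap on samples per class.
#' @param k Neighbourhood size the model will use (default 45).
#' @param seed Integer seed for the subsampling.
#' @return An object of class `knn_model`: `features` (n x d matrix),
#'   `classes` (integer 1 = CSF, 2 = GM, 3 = WM), `k`, `tie_rule`.
#' @export
sample_training_set <- function(image, pmap, prob_threshold = 1.0,
                                max_per_class = 2000, k = 45, seed = 1L) {
  channels <- if (inherits(image, "image_volume")) list(image) else image
  feats_full <- do.call(cbind, lapply(channels, function(ch) as.numeric(ch$data)))
  assert_that(all(is.finite(feats_full)), "features must be finite")
  probs <- list(csf = pmap$csf, gm = pmap$gm, wm = pmap$wm)
  step <- 1 / pmap$n_atlases
  eps <- 1e-9
  take <- list()
  for (ci in seq_along(probs)) {
    cname <- names(probs)[ci]
    thr <- prob_threshold
    idx <- which(as.numeric(probs[[ci]]) >= thr - eps)
    # fallback floor is one atlas vote (1/n): below that, "candidates"
    # would include voxels no atlas ever assigned to the class
    while (length(idx) < k && thr >= 2 * step - eps) {
      thr <- thr - step
      warning(sprintf(
        "class %s: fewer than k candidates at threshold; lowered to %.3f",
        cname, thr), call. = FALSE)
      idx <- which(as.numeric(probs[[ci]]) >= thr - eps)
    }
    assert_that(length(idx) >= k,
                sprintf("class %s has fewer than k = %d training candidates",
                        cname, k))
    if (length(idx) > max_per_class) {
      idx <- withr::with_seed(derive_seed(seed, ci),
                              sort(sample(idx, max_per_class)))
    }
    take[[ci]] <- idx
  }
  features <- do.call(rbind, lapply(take, function(idx)
    feats_full[idx, , drop = FALSE]))
  classes <- rep(seq_along(take), vapply(take, length, integer(1)))
  structure(list(features = features, classes = as.integer(classes),
                 k = as.integer(k),
                 tie_rule = paste("all samples within the k-th smallest distance;",
                                  "majority vote; ties by smaller mean",
                                  "neighbour distance, then CSF < GM < WM")),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k = %d, %d samples (%s), %d feature(s)\n",
              x$k, nrow(x$features),
              paste(table(factor(x$classes, 1:3, c("CSF", "GM", "WM"))),
                    collapse = "/"),
              ncol(x$features)))
  invisible(x)
}

# Neighbour semantics: the neighbourhood of a query is every training
# sample whose distance is <= the k-th smallest distance (distance ties
# included), which makes the classification independent of sample order
# and lets a brute-force scan reproduce it exactly.
knn_classify_1d <- function(train, cls, k, q) {
  ord <- order(train)
  t_s <- train[ord]; c_s <- cls[ord]
  n <- length(t_s)
  # prefix sums per class of counts and values
  pc <- sapply(1:3, function(c) cumsum(c_s == c))
  pv <- sapply(1:3, function(c) cumsum(t_s * (c_s == c)))
  pref <- function(P, i) {  # guarded prefix read, index 0 -> 0
    out <- matrix(0, length(i), ncol(P))
    pos <- i >= 1
    out[pos, ] <- P[i[pos], , drop = FALSE]
    out
  }

  m <- length(q)
  lo <- findInterval(q, t_s)      # candidates t_s[lo] (left), t_s[lo+1] (right)
  hi <- lo + 1L
  kth <- numeric(m)
  for (s in seq_len(k)) {
    dl <- ifelse(lo >= 1, q - t_s[pmax(lo, 1)], Inf)
    dr <- ifelse(hi <= n, t_s[pmin(hi, n)] - q, Inf)
    pick_left <- dl <= dr
    kth <- pmin(dl, dr)
    lo <- lo - as.integer(pick_left)
    hi <- hi + as.integer(!pick_left)
  }
  # widen to include all distance ties with the k-th neighbour
  repeat {
    grow_l <- lo >= 1 & (q - ifelse(lo >= 1, t_s[pmax(lo, 1)], NA)) <= kth
    grow_l[is.na(grow_l)] <- FALSE
    grow_r <- hi <= n & (ifelse(hi <= n, t_s[pmin(hi, n)], NA) - q) <= kth
    grow_r[is.na(grow_r)] <- FALSE
    if (!any(grow_l | grow_r)) break
    lo <- lo - as.integer(grow_l)
    hi <- hi + as.integer(grow_r)
  }
  lo <- lo + 1L; hi <- hi - 1L   # window [lo, hi] inclusive
  counts <- pref(pc, hi) - pref(pc, lo - 1L)
  top <- max.col(counts, ties.method = "first")
  nt <- rowSums(counts == counts[cbind(seq_len(m), top)])
  tied <- which(nt > 1)
  if (length(tied)) {
    # mean |t - q| per class over the window, via value prefix sums split at q
    split <- findInterval(q, t_s)
    for (i in tied) {
      w_lo <- lo[i]; w_hi <- hi[i]; qq <- q[i]
      sp <- min(max(split[i], w_lo - 1L), w_hi)
      best <- 0L; best_mean <- Inf
      for (c in 1:3) {
        cnt <- counts[i, c]
        if (cnt == 0 || cnt < max(counts[i, ])) next
        nl <- (if (sp >= 1) pc[sp, c] else 0) - (if (w_lo - 1 >= 1) pc[w_lo - 1, c] else 0)
        sl <- (if (sp >= 1) pv[sp, c] else 0) - (if (w_lo - 1 >= 1) pv[w_lo - 1, c] else 0)
        nr <- (if (w_hi >= 1) pc[w_hi, c] else 0) - (if (sp >= 1) pc[sp, c] else 0)
        sr <- (if (w_hi >= 1) pv[w_hi, c] else 0) - (if (sp >= 1) pv[sp, c] else 0)
        dist_sum <- (qq * nl - sl) + (sr - qq * nr)
        mean_d <- dist_sum / cnt
        if (mean_d < best_mean - 1e-12) { best <- c; best_mean <- mean_d }
      }
      top[i] <- best
    }
  }
  top
}

knn_classify_nd <- function(train, cls, k, q, chunk = 2000L) {
  m <- nrow(q)
  out <- integer(m)
  for (start in seq(1, m, by = chunk)) {
    idx <- start:min(start + chunk - 1, m)
    d2 <- outer(rowSums(q[idx, , drop = FALSE]^2), rowSums(train^2), "+") -
      2 * q[idx, , drop = FALSE] %*% t(train)
    for (r in seq_along(idx)) {
      dd <- sqrt(pmax(d2[r, ], 0))
      kth <- sort(dd, partial = k)[k]
      nb <- dd <= kth
      counts <- vapply(1:3, function(c) sum(nb & cls == c), numeric(1))
      top <- which(counts == max(counts))
      if (length(top) > 1) {
        md <- vapply(top, function(c) mean(dd[nb & cls == c]), numeric(1))
        top <- top[md == min(md)]
      }
      out[idx[r]] <- top[1]
    }
  }
  out
}

#' Segment brain tissue with a subject-trained kNN classifier
#'
#' Classifies every voxel inside the intracranial mask into CSF, GM or WM
#' by majority vote among the nearest training samples in intensity
#' space; voxels outside the mask are background. The neighbourhood of a
#' query is every training sample within the k-th smallest distance
#' (distance ties included, so the result is independent of training
#' sample order); vote ties go to the class with the smaller mean
#' neighbour distance, then to the fixed order CSF < GM < WM. All
#' intracranial voxels are forced into a tissue class — background is not
#' a class inside the mask.
#'
#' @param image [image_volume()] or list of channel volumes (the same
#'   bias-corrected input used for training).
#' @param model A `knn_model` from [sample_training_set()].
#' @param icv_mask Binary [image_volume()] intracranial mask on the image
#'   grid.
#' @return A [label_volume()].
#' @export
knn_segment <- function(image, model, icv_mask) {
  channels <- if (inherits(image, "image_volume")) list(image) else image
  geom <- channels[[1]]
  assert_that(all(dim(icv_mask$data) == dim(geom$data)),
              "icv_mask must be on the image grid")
  counts <- table(factor(model$classes, levels = 1:3))
  assert_that(all(counts >= model$k),
              sprintf("k = %d exceeds the sample count of class %s",
                      model$k, paste(names(counts)[counts < model$k],
                                     collapse = ", ")))
  inside <- which(icv_mask$data != 0)
  labels <- integer(length(geom$data))
  if (length(inside)) {
    q <- do.call(cbind, lapply(channels, function(ch) as.numeric(ch$data)[inside]))
    pred <- if (ncol(q) == 1) {
      knn_classify_1d(model$features[, 1], model$classes, model$k, q[, 1])
    } else {
      knn_classify_nd(model$features, model$classes, model$k, q)
    }
    labels[inside] <- pred
  }
  label_volume(array(labels, dim = dim(geom$data)), geom$spacing,
               geom$origin, geom$direction)
}

#' Tissue volumes in millilitres from a label volume
#'
#' Sums voxels per tissue and converts counts to ml via the voxel volume.
#' The identities `icv_ml = csf_ml + gm_ml + wm_ml` and
#' `brain_ml = gm_ml + wm_ml` hold exactly by construction. When a
#' cerebrum mask is supplied, the cerebrum-restricted brain volume is
#' reported alongside.
#'
#' @param labels A [label_volume()].
#' @param cerebrum_mask Optional binary [image_volume()].
#' @param pseudo_id,age,gender,group Optional annotation columns.
#' @param header Optional [header_record()] supplying scanner covariates.
#' @return A one-row tibble (a biomarker record): `pseudo_id`, `age`,
#'   `gender`, `group`, scanner covariates, `csf_ml`, `gm_ml`, `wm_ml`,
#'   `brain_ml`, `icv_ml`, `cerebrum_brain_ml`.
#' @export
compute_volumes <- function(labels, cerebrum_mask = NULL, pseudo_id = NA_character_,
                            age = NA_real_, gender = NA_character_,
                            group = NA_character_, header = NULL) {
  vv <- voxel_volume(labels) / 1000  # ml per voxel
  lab <- labels$data
  csf <- sum(lab == 1L) * vv
  gm <- sum(lab == 2L) * vv
  wm <- sum(lab == 3L) * vv
  cer <- if (!is.null(cerebrum_mask)) {
    sum(lab >= 2L & cerebrum_mask$data != 0) * vv
  } else NA_real_
  tibble::tibble(
    pseudo_id = pseudo_id, age = age, gender = gender, group = group,
    scanner_model = if (!is.null(header)) header$model else NA_character_,
    field_strength = if (!is.null(header)) header$field_strength else NA_real_,
    sequence = if (!is.null(header)) classify_sequence(header)$class else NA_character_,
    csf_ml = csf, gm_ml = gm, wm_ml = wm,
    brain_ml = gm + wm, icv_ml = csf + gm + wm,
    cerebrum_brain_ml = cer)
}

#' One-call tissue segmentation of an examination volume
#'
#' The full biomarker-extraction stage: bias-field correction,
#' atlas-probability map, majority-vote intracranial and cerebrum masks
#' (threshold 0.8), unanimity-threshold training-sample extraction, kNN
#' segmentation, and volume computation.
#'
#' @param image Subject [image_volume()] (a single channel, or a list of
#'   channels for PDw + T2w input; the first channel drives registration).
#' @param atlases An `atlas_set`.
#' @param config A [reg_config()].
#' @param k,max_per_class,prob_threshold kNN training parameters.
#' @param icv_mask_threshold Majority-vote threshold fusing the
#'   transformed intracranial masks. The default 0.5 is the unbiased
#'   median-surface fusion: at coarse voxel sizes a high vote threshold
#'   erodes the outer CSF shell and biases ICV low.
#' @param cerebrum_mask_threshold Majority-vote threshold for the cerebrum
#'   (skull-stripping) mask, 0.8 by convention.
#' @param seed Integer seed for the training subsample.
#' @param nonrigid Run the non-rigid registration refinement.
#' @return `list(record, labels, pmap, icv_mask, cerebrum_mask, corrected)`.
#' @export
segment_examination <- function(image, atlases, config = reg_config(),
                                k = 45, max_per_class = 2000,
                                prob_threshold = 1.0,
                                icv_mask_threshold = 0.5,
                                cerebrum_mask_threshold = 0.8,
                                seed = 1L, nonrigid = TRUE) {
  channels <- if (inherits(image, "image_volume")) list(image) else image
  corrected <- lapply(channels, function(ch) correct_bias(ch)$image)
  pmap <- build_probability_map(atlases, corrected[[1]], config,
                                nonrigid = nonrigid)
  icv_mask <- majority_mask(pmap$icv_masks, icv_mask_threshold)
  cerebrum_mask <- majority_mask(pmap$cerebrum_masks, cerebrum_mask_threshold)
  input <- if (length(corrected) == 1) corrected[[1]] else corrected
  model <- sample_training_set(input, pmap, prob_threshold = prob_threshold,
                               max_per_class = max_per_class, k = k,
                               seed = seed)
  labels <- knn_segment(input, model, icv_mask)
  record <- compute_volumes(labels, cerebrum_mask)
  list(record = record, labels = labels, pmap = pmap, icv_mask = icv_mask,
       cerebrum_mask = cerebrum_mask, corrected = corrected)
}
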