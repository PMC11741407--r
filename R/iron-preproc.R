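#' Construct a 4D T2*-weighted volume series
#'
#' @param intensities 4D numeric array (x, y, z, t) of echo-planar volumes.
#' @param fd Per-volume framewise displacement in mm (length = t).
#' @param session,batch Identifiers carried through to ROI tables.
#' @param coverage_mask Optional 3D logical mask; by default the coverage
#'   map is the set of voxels that are non-zero in every volume.
#' @return List of class `volume_series`.
#' @export
volume_series <- function(intensities, fd, session = "s1", batch = "A",
                          coverage_mask = NULL) {
  stopifnot(length(dim(intensities)) == 4, length(fd) == dim(intensities)[4])
  if (is.null(coverage_mask)) {
    coverage_mask <- apply(intensities != 0, c(1, 2, 3), all)
  }
  if (!any(coverage_mask)) stop("empty coverage mask", call. = FALSE)
  structure(
    list(intensities = intensities, fd = fd, session = session,
         batch = batch, coverage_mask = coverage_mask),
    class = "volume_series"
  )
}

#' Motion-censor volumes by framewise displacement
#'
#' Volumes with FD strictly greater than the threshold (default 0.3 mm) are
#' excluded.
#'
#' @param x A [volume_series()] or a numeric FD vector.
#' @param threshold FD threshold in mm (default 0.3).
#' @return Logical keep-mask, `TRUE` for retained volumes.
#' @export
censor_volumes <- function(x, threshold = 0.3) {
  fd <- if (inherits(x, "volume_series")) x$fd else x
  stopifnot(is.numeric(fd), all(is.finite(fd)))
  keep <- fd <= threshold
  if (!any(keep)) {
    stop("all ", length(fd), " volumes exceed the FD threshold of ",
         threshold, " mm", call. = FALSE)
  }
  keep
}

#' Compute the normalized T2*-weighted (nT2*w) map
#'
#' Each retained volume is z-score normalized over the coverage mask
#' (subtract the within-mask mean, divide by the within-mask SD), making
#' the result invariant to per-volume positive-affine intensity changes.
#' The normalized volumes are then aggregated voxelwise with the median
#' (lower median for even counts), yielding one nT2*w map per session.
#' Lower nT2*w means more tissue iron.
#'
#' @param series A [volume_series()].
#' @param keep Logical keep-mask from [censor_volumes()]; defaults to
#'   censoring at 0.3 mm.
#' @return 3D array: nT2*w within the coverage mask, `NA` outside.
#' @export
compute_nt2w_map <- function(series, keep = censor_volumes(series)) {
  stopifnot(inherits(series, "volume_series"),
            length(keep) == length(series$fd))
  idx <- which(keep)
  if (length(idx) == 0) stop("no retained volumes", call. = FALSE)
  mask <- series$coverage_mask
  zmat <- vapply(idx, function(t) {
    v <- series$intensities[, , , t][mask]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("volume ", t, " has zero within-mask intensity variance",
           call. = FALSE)
    }
    (v - mean(v)) / s
  }, numeric(sum(mask)))
  # lower median per voxel: for even counts take the lower middle value
  med <- apply(zmat, 1, stats::quantile, probs = 0.5, type = 1, names = FALSE)
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- med
  out
}

#' Extract per-region nT2*w means from a map
#'
#' @param map 3D nT2*w map from [compute_nt2w_map()].
#' @param atlas 3D integer array of region labels on the same grid.
#' @param regions Named list mapping region names to one or more atlas
#'   labels; hemispheric labels listed under one name are pooled (the mean
#'   runs over the union of their voxels).
#' @param session,batch Identifiers for the output rows.
#' @return Tibble with `region`, `nT2w`, `n_voxels`, `session`, `batch`.
#' @export
extract_roi <- function(map, atlas, regions, session = "s1", batch = "A") {
  stopifnot(identical(dim(map), dim(atlas)))
  purrr::map_dfr(names(regions), function(r) {
    vox <- map[atlas %in% regions[[r]]]
    if (length(vox) == 0) {
      stop("region '", r, "' matches no atlas voxels", call. = FALSE)
    }
    tibble::tibble(region = r, nT2w = mean(vox, na.rm = TRUE),
                   n_voxels = length(vox), session = session, batch = batch)
  })
}

#' Harmonize ROI measures across scanner batches
#'
#' Simplified location-scale harmonization with empirical shrinkage: per
#' region, batch mean offsets and residual-SD ratios are estimated from a
#' linear model that adjusts for biological covariates; batch parameters
#' are then shrunk toward their across-region means (normal-normal
#' empirical-Bayes weights) and removed, rescaling each batch's residual SD
#' to the pooled SD. Covariate (e.g. age, sex) relationships are preserved.
#'
#' @param measures Tibble with one row per region x session, containing the
#'   value column, `region`, the batch column, and the covariates.
#' @param value Name of the value column (default `"nT2w"`).
#' @param batch Name of the batch column (default `"batch"`).
#' @param covariates Covariate column names whose associations must be
#'   preserved (default `c("age", "sex")`; may be empty).
#' @param min_n Minimum observations per batch for shrinkage (default 5);
#'   smaller batches are harmonized with their raw estimates, with a
#'   warning.
#' @return The input tibble with the value column replaced by harmonized
#'   values and the original kept as `<value>_raw`.
#' @export
harmonize_batches <- function(measures, value = "nT2w", batch = "batch",
                              covariates = c("age", "sex"), min_n = 5) {
  stopifnot(all(c(value, batch, "region") %in% names(measures)))
  batches <- sort(unique(as.character(measures[[batch]])))
  if (length(batches) < 2) stop("need at least 2 batches", call. = FALSE)
  small <- measures |>
    dplyr::count(.data$region, .data[[batch]]) |>
    dplyr::filter(.data$n < min_n)
  if (nrow(small) > 0) {
    warning("batch(es) with fewer than ", min_n,
            " observations are harmonized without shrinkage", call. = FALSE)
  }
  covariates <- intersect(covariates, names(measures))
  regions <- unique(measures$region)

  # per region: covariate-adjusted batch offsets and residual SD ratios
  est <- purrr::map(regions, function(r) {
    d <- measures[measures$region == r, , drop = FALSE]
    d$.b <- factor(as.character(d[[batch]]), levels = batches)
    rhs <- paste(c(covariates, ".b"), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste(value, "~", rhs)), data = d)
    cf <- stats::coef(fit)
    raw <- c(0, cf[paste0(".b", batches[-1])])     # offsets vs first batch
    raw[is.na(raw)] <- 0
    n_b <- as.numeric(table(d$.b)[batches])
    gamma <- raw - sum(n_b * raw) / sum(n_b)       # size-weighted centering
    res <- stats::resid(fit)
    delta <- vapply(batches, function(b) {
      rb <- res[d$.b == b]
      if (length(rb) > 1) stats::sd(rb) else NA_real_
    }, numeric(1))
    sigma <- stats::sd(res)
    d_ref <- d
    d_ref$.b <- factor(rep(batches[1], nrow(d)), levels = batches)
    no_batch <- stats::predict(fit, newdata = d_ref)
    # remove the reference batch's own (centered) offset from the baseline
    baseline <- no_batch - gamma[1]
    list(region = r, gamma = gamma, delta = delta, sigma = sigma,
         n_b = n_b, rows = which(measures$region == r),
         b = as.character(d[[batch]]), y = d[[value]], baseline = baseline)
  })

  gmat <- do.call(rbind, lapply(est, `[[`, "gamma"))
  lmat <- do.call(rbind, lapply(est, function(e) log(e$delta / e$sigma)))
  colnames(gmat) <- colnames(lmat) <- batches

  shrink <- function(vals, samp_var) {
    # normal-normal EB: shrink region-level estimates toward their mean
    m <- mean(vals)
    tau2 <- max(stats::var(vals) - mean(samp_var, na.rm = TRUE), 0)
    w <- tau2 / (tau2 + samp_var)
    w[!is.finite(w)] <- 1
    w * vals + (1 - w) * m
  }

  out_val <- measures[[value]]
  for (j in seq_along(batches)) {
    b <- batches[j]
    samp_var_g <- vapply(est, function(e) e$sigma^2 / max(e$n_b[j], 1),
                         numeric(1))
    g_star <- shrink(gmat[, j], samp_var_g)
    samp_var_l <- vapply(est, function(e) 1 / (2 * max(e$n_b[j] - 1, 1)),
                         numeric(1))
    l_star <- shrink(lmat[, j], samp_var_l)
    for (i in seq_along(est)) {
      e <- est[[i]]
      if (e$n_b[j] < min_n) {  # too small to borrow strength: raw estimates
        g_use <- gmat[i, j]
        s_use <- exp(lmat[i, j])
      } else {
        g_use <- g_star[i]
        s_use <- exp(l_star[i])
      }
      rows_b <- e$rows[e$b == b]
      rel <- match(rows_b, e$rows)
      adj <- (measures[[value]][rows_b] - e$baseline[rel] - g_use) / s_use +
        e$baseline[rel]
      out_val[rows_b] <- adj
    }
  }
  measures[[paste0(value, "_raw")]] <- measures[[value]]
  measures[[value]] <- out_val
  measures
}
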