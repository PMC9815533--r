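#' Uniform flux sampling of the steady-state polytope
#'
#' Draws flux vectors approximately uniformly from
#' `{v : S v = 0, lb <= v <= ub}` with an artificially-centered hit-and-run
#' walk: warm-up points are the flux-variability vertices, directions are
#' differences between a randomly chosen stored point and the running
#' center (so degenerate dimensions are never proposed), and step lengths
#' are uniform on the feasible chord. The walk runs in the null space of
#' `S` restricted by the pinned (`lb == ub`) fluxes, so every sample
#' satisfies the mass balance exactly up to numerical tolerance.
#'
#' Bounds beyond the conventional +-1000 "unbounded" sentinels are clamped
#' to +-1000 before sampling so the polytope is bounded. Fluxes whose
#' feasible range is a single point are reported with standard deviation 0.
#'
#' @param model A [gem] or community model; must be feasible.
#' @param n Number of samples to keep (default 5000, the customary scale
#'   for flux-sampling summaries).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @param thin Keep every `thin`-th accepted step.
#' @param burn Warm-up steps before recording; defaults to
#'   `min(100 * dim, 2000)` where `dim` is the polytope dimension.
#' @return An object of class `flux_sample`: `summary` (tibble with
#'   `reaction`, `mean`, `sd`), `samples` (n x reactions matrix), `n`,
#'   `seed`. `tidy()` returns the summary tibble.
#' @export
sample_fluxes <- function(model, n = 5000, seed = NULL, thin = 5,
                          burn = NULL) {
  model <- as_gem(model)
  stopifnot(n >= 1)
  lb <- pmax(model$reactions$lb, -1000)
  ub <- pmin(model$reactions$ub, 1000)
  ids <- model$reactions$id
  S <- stoich_matrix(model)
  nr <- ncol(S)

  fva <- flux_variability(set_all_bounds(model, lb, ub))
  fva <- fva[match(ids, fva$reaction), ]

  # warm-up points: FVA vertices (min and max argument of every reaction)
  pts <- warmup_points(model, S, lb, ub, ids)
  center <- colMeans(pts)

  # walk in the subspace of reactions whose feasible range has width
  widths <- fva$max - fva$min
  movable <- widths > 1e-9
  burn <- burn %||% min(100L * max(sum(movable), 1L), 2000L)

  run <- function() {
    x <- center
    keep <- matrix(NA_real_, n, nr, dimnames = list(NULL, ids))
    kept <- 0L
    step <- 0L
    stalls <- 0L
    while (kept < n) {
      step <- step + 1L
      if (stalls > 10000L) {
        stop("hit-and-run failed to move; polytope may be degenerate")
      }
      d <- pts[sample.int(nrow(pts), 1L), ] - center
      nrm <- sqrt(sum(d * d))
      if (nrm < 1e-12) { stalls <- stalls + 1L; next }
      d <- d / nrm
      # feasible chord: lb <= x + t d <= ub on moving coordinates
      act <- abs(d) > 1e-12
      r1 <- (lb[act] - x[act]) / d[act]
      r2 <- (ub[act] - x[act]) / d[act]
      tmin <- max(pmin(r1, r2))
      tmax <- min(pmax(r1, r2))
      if (!is.finite(tmin) || !is.finite(tmax) || tmax - tmin < 1e-12) {
        stalls <- stalls + 1L
        next
      }
      stalls <- 0L
      t <- stats::runif(1, tmin, tmax)
      x <- x + t * d
      center <- center + (x - center) / (step + nrow(pts))
      if (step > burn && (step - burn) %% thin == 0L) {
        kept <- kept + 1L
        keep[kept, ] <- x
      }
    }
    keep
  }
  samples <- if (!any(movable)) {
    # the feasible set is a single point: every sample is that point
    matrix(rep(center, each = n), n, nr, dimnames = list(NULL, ids))
  } else if (is.null(seed)) {
    run()
  } else {
    withr::with_seed(seed, run())
  }

  means <- colMeans(samples)
  sds <- apply(samples, 2, stats::sd)
  sds[widths <= 1e-9] <- 0
  structure(
    list(summary = tibble::tibble(reaction = ids, mean = means, sd = sds),
         samples = samples, n = n, seed = seed,
         fva = fva),
    class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat(sprintf("<flux_sample> %d samples x %d reactions (seed %s)\n",
              x$n, ncol(x$samples),
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' @rdname sample_fluxes
#' @param x A `flux_sample`.
#' @param ... Unused.
#' @method tidy flux_sample
#' @export
tidy.flux_sample <- function(x, ...) x$summary

set_all_bounds <- function(model, lb, ub) {
  model$reactions$lb <- lb
  model$reactions$ub <- ub
  model
}

warmup_points <- function(model, S, lb, ub, ids) {
  zero <- rep(0, nrow(S))
  pts <- list()
  for (j in seq_along(ids)) {
    obj <- numeric(ncol(S)); obj[j] <- 1
    for (maxi in c(TRUE, FALSE)) {
      r <- solve_lp(obj, S, zero, lb, ub, maximize = maxi)
      if (r$status != "optimal") stop("warm-up LP failed for '", ids[j], "'")
      pts[[length(pts) + 1L]] <- r$x
    }
  }
  do.call(rbind, pts)
}
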