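# Distances between datasets: bounded-kernel MMD (the default), weighted L2
# on summary vectors, and distance clipping.

#' Gaussian kernel specification
#'
#' The Gaussian (RBF) kernel `k(x, y) = exp(-||x - y||^2 / (2 l^2))` with
#' bandwidth `l`. Its values lie in (0, 1], so the kernel is uniformly
#' bounded by `B_k = 1` for every bandwidth; this bound is what makes the
#' MMD distance's sensitivity finite and hence the privacy calibration
#' possible.
#'
#' @param bandwidth Positive bandwidth `l`, or the string `"median"` to
#'   request the median heuristic (resolved against pseudo-data at run time;
#'   see [median_heuristic_bandwidth()]).
#' @param family Kernel family; only `"gaussian"` is available.
#' @return An object of class `abcdp_kernel` with fields `family`,
#'   `bandwidth` and `bound` (the uniform bound `B_k`).
#' @seealso [gaussian_kernel()], [mmd_distance()]
#' @export
#' @examples
#' kernel_spec(1.5)
#' kernel_spec("median")
kernel_spec <- function(bandwidth = "median", family = "gaussian") {
  family <- match.arg(family)
  if (!(identical(bandwidth, "median"))) {
    check_positive_scalar(bandwidth, "bandwidth")
  }
  structure(
    list(family = family, bandwidth = bandwidth, bound = 1),
    class = "abcdp_kernel"
  )
}

#' @export
print.abcdp_kernel <- function(x, ...) {
  bw <- if (identical(x$bandwidth, "median")) "median heuristic" else
    format(x$bandwidth)
  cat("Gaussian kernel: bandwidth =", bw, "; bound B_k =", x$bound, "\n")
  invisible(x)
}

#' Evaluate the Gaussian kernel at a pair of points
#'
#' @param x,y Numeric vectors of equal length (single points).
#' @param bandwidth Positive bandwidth `l`.
#' @return `exp(-||x - y||^2 / (2 * bandwidth^2))`, a value in (0, 1].
#' @export
#' @examples
#' gaussian_kernel(0, 0, 1)                    # 1
#' gaussian_kernel(0, sqrt(2), 1)              # exp(-1)
gaussian_kernel <- function(x, y, bandwidth) {
  check_positive_scalar(bandwidth, "bandwidth")
  if (length(x) != length(y)) {
    stop_invalid("`x` and `y` must have the same dimension")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_invalid("kernel inputs must be finite")
  }
  exp(-sum((x - y)^2) / (2 * bandwidth^2))
}

# Mean kernel value over all cross pairs of two datasets; thin wrapper over
# the compiled double loop.
gauss_kernel_mean <- function(X, Y, bandwidth) {
  gauss_kernel_mean_cpp(X, Y, bandwidth)
}

resolve_bandwidth <- function(kernel, context = "mmd") {
  if (identical(kernel$bandwidth, "median")) {
    stop_invalid("kernel bandwidth is set to \"median\" but has not been ",
                 "resolved; call median_heuristic_bandwidth() on the ",
                 "pseudo-data first")
  }
  kernel$bandwidth
}

#' Biased (V-statistic) squared MMD estimator
#'
#' Computes the plug-in estimator of the squared maximum mean discrepancy
#' between the empirical distributions of two datasets,
#' \deqn{\widehat{MMD}^2 = \frac{1}{m^2}\sum_{i,j} k(x_i,x_j)
#'   + \frac{1}{n^2}\sum_{i,j} k(y_i,y_j)
#'   - \frac{2}{mn}\sum_{i,j} k(x_i,y_j),}
#' with diagonal terms included. This V-statistic equals the squared RKHS
#' norm of the difference of empirical mean embeddings, so it is always
#' nonnegative (unlike the unbiased U-statistic), which keeps its square
#' root well defined.
#'
#' @param X,Y Datasets (see [as_dataset()]); may have different numbers of
#'   rows but must share the dimension d.
#' @param kernel A [kernel_spec()] with a numeric bandwidth.
#' @return The nonnegative squared MMD estimate.
#' @export
#' @examples
#' X <- matrix(rnorm(20), ncol = 2)
#' mmd2_biased(X, X, kernel_spec(1))   # 0
mmd2_biased <- function(X, Y, kernel = kernel_spec(1)) {
  X <- as_dataset(X); Y <- as_dataset(Y)
  if (ncol(X) != ncol(Y)) {
    stop_invalid("datasets have mismatched dimensions: ",
                 ncol(X), " vs ", ncol(Y))
  }
  l <- resolve_bandwidth(kernel)
  v <- gauss_kernel_mean(X, X, l) + gauss_kernel_mean(Y, Y, l) -
    2 * gauss_kernel_mean(X, Y, l)
  # floating cancellation can leave a tiny negative residue
  if (v < 0 && v > -1e-12) v <- 0
  v
}

#' MMD distance between two datasets
#'
#' The square root of [mmd2_biased()]. With a kernel uniformly bounded by
#' `B_k`, the distance is bounded above by `2 * sqrt(B_k)` for any pair of
#' datasets, and replacing a single record of an N-point dataset moves it
#' by at most `2 * sqrt(B_k) / N` — the sensitivity used to calibrate the
#' privacy noise (see [mmd_sensitivity()]).
#'
#' @inheritParams mmd2_biased
#' @return A nonnegative distance.
#' @export
#' @examples
#' X <- matrix(c(0, 1), ncol = 1); Y <- matrix(c(10, 11), ncol = 1)
#' mmd_distance(X, Y, kernel_spec(1))
mmd_distance <- function(X, Y, kernel = kernel_spec(1)) {
  sqrt(max(mmd2_biased(X, Y, kernel), 0))
}

#' Median-heuristic kernel bandwidth from pseudo-data
#'
#' Sets the Gaussian kernel bandwidth to the median of the pairwise
#' Euclidean distances among pooled pseudo-data points. Only simulated
#' (public) data enter the computation — the private observations are never
#' touched, so the heuristic carries no privacy cost. When the pool exceeds
#' `max_points` points, a reproducible subsample bounds the quadratic pair
#' enumeration.
#'
#' @param pseudo_datasets A single dataset or a list of datasets to pool.
#' @param max_points Cap on the number of pooled points entering the pair
#'   enumeration (default 1000).
#' @param subsample_seed Seed for the subsample when the cap binds; the
#'   caller's RNG stream is left untouched.
#' @return The positive median pairwise distance.
#' @export
#' @examples
#' median_heuristic_bandwidth(matrix(c(0, 1, 2), ncol = 1))  # 1
median_heuristic_bandwidth <- function(pseudo_datasets, max_points = 1000,
                                       subsample_seed = 1L) {
  if (!is.list(pseudo_datasets)) pseudo_datasets <- list(pseudo_datasets)
  pooled <- do.call(rbind, lapply(pseudo_datasets, as_dataset))
  if (nrow(pooled) < 2L) {
    stop_invalid("need at least two pooled points for the median heuristic")
  }
  if (nrow(pooled) > max_points) {
    keep <- with_preserved_seed(subsample_seed,
                                sample.int(nrow(pooled), max_points))
    pooled <- pooled[keep, , drop = FALSE]
  }
  bw <- median(stats::dist(pooled))
  if (!is.finite(bw) || bw <= 0) {
    stop_invalid("degenerate pseudo-data: median pairwise distance is zero")
  }
  bw
}

#' Weighted L2 distance between summary vectors
#'
#' `sqrt(sum(w_j * (s1_j - s2_j)^2))`: the distance used when comparing
#' datasets through a fixed vector of summary statistics rather than through
#' a kernel. It has no intrinsic bound, so for private use it must be paired
#' with a clipping bound and a user-supplied sensitivity.
#'
#' @param s1,s2 Numeric vectors of equal length.
#' @param weights Nonnegative weights, recycled scalar allowed; default 1
#'   (ordinary Euclidean distance).
#' @return The nonnegative weighted distance.
#' @export
weighted_l2_distance <- function(s1, s2, weights = 1) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) != length(s2)) {
    stop_invalid("summary vectors have mismatched lengths: ",
                 length(s1), " vs ", length(s2))
  }
  if (length(weights) == 1L) weights <- rep(weights, length(s1))
  if (length(weights) != length(s1) || any(weights < 0)) {
    stop_invalid("`weights` must be nonnegative and match the summary length")
  }
  sqrt(sum(weights * (s1 - s2)^2))
}

#' Clip a distance at a bound
#'
#' Distances without an intrinsic bound (e.g. weighted L2 on raw counts) are
#' clipped at `C` before privatization so that an artificial sensitivity
#' bound holds: `min(rho, C)`. Idempotent.
#'
#' @param rho Nonnegative distance value(s); vectorized.
#' @param C Positive clipping bound.
#' @return `pmin(rho, C)`.
#' @export
#' @examples
#' clip_distance(c(50, 350), 200)  # 50, 200
clip_distance <- function(rho, C) {
  check_positive_scalar(C, "C")
  pmin(rho, C)
}

#' Distance specification
#'
#' Bundles the distance family with its parameters and the sensitivity used
#' for privacy calibration. For `kind = "mmd"` the sensitivity may be
#' `"auto"`, in which case it is derived from the size N of the private
#' dataset as `2 * sqrt(B_k) / N`. For `kind = "weighted_l2"` there is no
#' derivable bound: a clipping bound and an explicit numeric `sensitivity`
#' must be supplied — the package refuses to guess one.
#'
#' @param kind `"mmd"` or `"weighted_l2"`.
#' @param kernel A [kernel_spec()] (MMD only).
#' @param weights Nonnegative summary weights (weighted L2 only).
#' @param clip Optional positive clipping bound `C` applied to the raw
#'   distance before any noise.
#' @param sensitivity `"auto"` (MMD only) or a positive number: the maximum
#'   change of the (clipped) distance when one record of the private dataset
#'   is replaced.
#' @return An object of class `abcdp_distance`.
#' @export
#' @examples
#' distance_spec("mmd", kernel = kernel_spec(1))
#' distance_spec("weighted_l2", weights = 1, clip = 200, sensitivity = 200)
distance_spec <- function(kind = c("mmd", "weighted_l2"),
                          kernel = kernel_spec(),
                          weights = 1,
                          clip = NULL,
                          sensitivity = "auto") {
  kind <- match.arg(kind)
  if (!is.null(clip)) check_positive_scalar(clip, "clip")
  if (kind == "mmd") {
    stopifnot(inherits(kernel, "abcdp_kernel"))
  } else {
    if (identical(sensitivity, "auto")) {
      stop_invalid("weighted_l2 distances have no derivable sensitivity; ",
                   "supply `sensitivity` explicitly (typically alongside a ",
                   "clipping bound)")
    }
  }
  if (!identical(sensitivity, "auto")) {
    check_positive_scalar(sensitivity, "sensitivity")
  }
  structure(
    list(kind = kind, kernel = if (kind == "mmd") kernel else NULL,
         weights = if (kind == "weighted_l2") weights else NULL,
         clip = clip, sensitivity = sensitivity),
    class = "abcdp_distance"
  )
}

#' @export
print.abcdp_distance <- function(x, ...) {
  cat("Distance:", x$kind,
      if (!is.null(x$clip)) paste0("(clipped at ", x$clip, ")"), "\n")
  if (x$kind == "mmd") print(x$kernel)
  cat("Sensitivity:",
      if (identical(x$sensitivity, "auto")) "auto (2*sqrt(B_k)/N)" else
        format(x$sensitivity), "\n")
  invisible(x)
}

# Resolve a distance spec against the observed dataset: fixes the bandwidth
# (median heuristic requires pseudo-data, supplied by the caller), and
# returns a closure rho(Y) with the observed self-term cached for MMD.
make_distance_fun <- function(spec, observed) {
  observed <- as_dataset(observed)
  clip <- spec$clip
  if (spec$kind == "mmd") {
    l <- resolve_bandwidth(spec$kernel)
    term_obs <- gauss_kernel_mean(observed, observed, l)
    function(Y) {
      Y <- as_dataset(Y)
      if (ncol(Y) != ncol(observed)) {
        stop_invalid("pseudo-dataset dimension ", ncol(Y),
                     " does not match observed dimension ", ncol(observed))
      }
      v <- term_obs + gauss_kernel_mean(Y, Y, l) -
        2 * gauss_kernel_mean(observed, Y, l)
      rho <- sqrt(max(v, 0))
      if (is.null(clip)) rho else min(rho, clip)
    }
  } else {
    s_obs <- as.numeric(observed)
    w <- spec$weights
    function(Y) {
      rho <- weighted_l2_distance(s_obs, as.numeric(Y), w)
      if (is.null(clip)) rho else min(rho, clip)
    }
  }
}

# Sensitivity of the (possibly clipped) distance for a private dataset of
# size N, as used by the privacy calibration.
resolve_sensitivity <- function(spec, N) {
  if (!identical(spec$sensitivity, "auto")) return(spec$sensitivity)
  if (spec$kind != "mmd") {
    stop_invalid("automatic sensitivity is only available for the MMD ",
                 "distance")
  }
  mmd_sensitivity(N, spec$kernel$bound)
}
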