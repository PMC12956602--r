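# Per-marker automatic gating with a two-component Gaussian mixture on
# log1p intensities, and the piecewise-linear rescaling that maps the gate
# to 0.5. The gate is placed at the intersection of the weighted component
# densities between the two means (default), or at the point where the
# posterior responsibility of the high component crosses 0.5.

#' Fit per-marker Gaussian-mixture gates
#'
#' For every marker a two-component univariate Gaussian mixture is fitted to
#' `log1p(intensity)` by EM ([mclust::Mclust()], equal- and unequal-variance
#' models selected by BIC). The gate is then located between the two
#' component means, and a monotone piecewise-linear map rescales intensities
#' so the marker minimum maps to 0, the gate to 0.5, and the maximum to 1.
#'
#' @param features A [feature_matrix()] of protein intensities.
#' @param markers Character vector of marker names to gate (default: all
#'   columns).
#' @param method Gate placement: `"density"` (equal weighted-density point,
#'   the default) or `"responsibility"` (posterior responsibility of the
#'   high component equals 0.5).
#' @param seed Integer seed for the EM initialisation.
#' @return A `gate_model`: per marker the component means, sds, weights,
#'   the gate (on the log1p scale), and the data range used by the rescale
#'   map.
#' @export
fit_gates <- function(features, markers = colnames(features),
                      method = c("density", "responsibility"), seed = 1L) {
  method <- match.arg(method)
  missing <- setdiff(markers, colnames(features))
  if (length(missing)) {
    zm_stop(paste0("markers absent from the feature matrix: ", paste(missing, collapse = ", ")),
      "zonemap_schema_error")
  }
  gates <- lapply(markers, function(mk) {
    v <- features[, mk]
    if (sum(v > 0) < 50) {
      zm_stop(sprintf("marker '%s' has fewer than 50 cells with positive intensity", mk),
        "zonemap_gating_error")
    }
    x <- log1p(v)
    if (stats::sd(x) == 0) {
      zm_stop(sprintf("marker '%s' is constant; cannot gate", mk), "zonemap_gating_error")
    }
    fit <- zm_with_seed(seed, suppressWarnings(
      Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE)
    ))
    if (is.null(fit)) {
      zm_stop(sprintf("mixture fit failed for marker '%s'", mk), "zonemap_gating_error")
    }
    mean_ <- as.numeric(fit$parameters$mean)
    var_ <- fit$parameters$variance$sigmasq
    if (length(var_) == 1) var_ <- rep(var_, 2)
    w <- as.numeric(fit$parameters$pro)
    o <- order(mean_)
    mean_ <- mean_[o]; var_ <- var_[o]; w <- w[o]
    gate <- .locate_gate(mean_, sqrt(var_), w, method)
    list(
      marker = mk,
      means = mean_, sds = sqrt(var_), weights = w,
      gate = gate, lo = min(x), hi = max(x)
    )
  })
  names(gates) <- markers
  structure(list(gates = gates, method = method, transform = "log1p", seed = seed),
    class = "gate_model")
}

# Gate between the two means: root of the weighted-density difference
# (density method) or of responsibility - 0.5. Falls back through the
# alternatives down to the midpoint if no sign change is found.
.locate_gate <- function(m, s, w, method) {
  dens_diff <- function(x) {
    w[1] * stats::dnorm(x, m[1], s[1]) - w[2] * stats::dnorm(x, m[2], s[2])
  }
  resp_diff <- function(x) {
    d1 <- w[1] * stats::dnorm(x, m[1], s[1])
    d2 <- w[2] * stats::dnorm(x, m[2], s[2])
    d2 / (d1 + d2) - 0.5
  }
  f <- if (method == "density") dens_diff else resp_diff
  lo <- m[1] + 1e-9; hi <- m[2] - 1e-9
  if (hi <= lo) return(mean(m))
  flo <- f(lo); fhi <- f(hi)
  if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
    return(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  }
  # density difference can be one-signed for very unequal weights; the
  # responsibility crossing is then the principled gate
  flo <- resp_diff(lo); fhi <- resp_diff(hi)
  if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
    return(stats::uniroot(resp_diff, c(lo, hi), tol = 1e-10)$root)
  }
  mean(m)
}

#' Rescale intensities through a fitted gate model
#'
#' Applies the per-marker piecewise-linear map on the log1p scale:
#' `[min, gate] -> [0, 0.5]` and `[gate, max] -> [0.5, 1]`, clamped to
#' `[0, 1]` for values outside the fitted range. A value exactly at the
#' gate maps to 0.5.
#'
#' @param model A `gate_model` from [fit_gates()].
#' @param features A [feature_matrix()] of raw intensities containing the
#'   gated markers.
#' @return A matrix of gated values in `[0, 1]` (cells x gated markers).
#' @export
rescale_gated <- function(model, features) {
  stopifnot(inherits(model, "gate_model"))
  markers <- names(model$gates)
  missing <- setdiff(markers, colnames(features))
  if (length(missing)) {
    zm_stop(paste0("markers absent from the feature matrix: ", paste(missing, collapse = ", ")),
      "zonemap_schema_error")
  }
  out <- matrix(NA_real_, nrow(features), length(markers),
    dimnames = list(rownames(features), markers))
  for (mk in markers) {
    g <- model$gates[[mk]]
    x <- log1p(features[, mk])
    lo <- min(g$lo, g$gate - 1e-12)
    hi <- max(g$hi, g$gate + 1e-12)
    below <- 0.5 * (x - lo) / (g$gate - lo)
    above <- 0.5 + 0.5 * (x - g$gate) / (hi - g$gate)
    r <- ifelse(x <= g$gate, below, above)
    out[, mk] <- pmin(pmax(r, 0), 1)
  }
  out
}
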