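#' Integer percentage comparison of two quantities
#'
#' Expresses `value` against `reference` as an integer percentage with
#' half-up rounding: ratio mode gives `round(100 * value / reference)`, loss
#' mode gives `round(100 * (1 - value / reference))`. For the same pair,
#' ratio + loss = 100 up to rounding.
#'
#' @param value,reference Quantities in the same units; `reference` > 0.
#' @param mode "ratio" or "loss".
#' @return Integer percent.
#' @export
#' @examples
#' percent_change(30.697, 66.816, "ratio")  # 46
#' percent_change(32.531, 61.900, "loss")   # 47
percent_change <- function(value, reference, mode = c("ratio", "loss")) {
  mode <- match.arg(mode)
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  pct <- if (mode == "ratio") 100 * value / reference
         else 100 * (1 - value / reference)
  as.integer(floor(pct + 0.5))  # half-up, not banker's rounding
}

#' Per-system means and standard errors
#'
#' @param data Data frame of per-site (or per-site-per-guild) responses.
#' @param responses Character vector of response column names.
#' @param system Grouping column (default "system"); an optional second
#'   grouping (e.g. guild) can be supplied via `by`.
#' @param by Optional extra grouping column name.
#' @return Long data frame: grouping columns, response, n, mean, se (NA and
#'   flagged when a cell holds a single site).
#' @export
summarize_by_system <- function(data, responses, system = "system", by = NULL) {
  groups <- c(system, by)
  split_idx <- split(seq_len(nrow(data)), data[groups], drop = TRUE)
  rows <- lapply(names(split_idx), function(key) {
    idx <- split_idx[[key]]
    meta <- data[idx[1], groups, drop = FALSE]
    do.call(rbind, lapply(responses, function(r) {
      v <- data[idx, r]
      cbind(meta,
            data.frame(response = r, n = length(v), mean = mean(v),
                       se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                       row.names = NULL))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n == 1))
    warning("standard error undefined for group(s) with a single site")
  out
}

bef_candidates <- function(richness_term, system_term, random_term) {
  list(
    full      = sprintf(".y ~ %s * %s %s", richness_term, system_term, random_term),
    additive  = sprintf(".y ~ %s + %s %s", richness_term, system_term, random_term),
    richness  = sprintf(".y ~ %s %s", richness_term, random_term),
    null      = sprintf(".y ~ 1 %s", random_term)
  )
}

#' Fit and select biodiversity--ecosystem-functioning models
#'
#' Regresses a response (total or per-guild energy flux by default) on
#' log10 species richness, transformation system and their interaction, with
#' a random landscape intercept, and performs AIC backward selection over the
#' candidate set {full, additive, richness-only, null}. The lowest-AIC model
#' is selected only when it improves on every simpler candidate by at least
#' `delta_aic` units; otherwise the simplest model within `delta_aic` of the
#' minimum is chosen. Gaussian responses may be log10-transformed
#' (`family = "lognormal"`); overdispersed counts (e.g. richness as a
#' response in community models) use a negative binomial GLMM.
#'
#' Models are fitted with maximum likelihood (`REML = FALSE`) so AIC values
#' are comparable across fixed-effect structures. When the random intercept
#' cannot be estimated (a single landscape, or a singular fit), the function
#' falls back to the corresponding fixed-effects model with a warning.
#'
#' @param data Data frame with the response, richness, system and landscape
#'   columns.
#' @param response Response column name (e.g. "flux_kg_ha_yr").
#' @param richness Richness column name; entered as log10(richness).
#' @param system,landscape Column names of the system factor and the random
#'   intercept grouping.
#' @param family "lognormal" (log10-transformed Gaussian), "gaussian", or
#'   "nbinom" (negative binomial counts).
#' @param delta_aic Minimum AIC improvement required to prefer a more complex
#'   model (default 2).
#' @return A `bef_fit`: list with `models`, `aic_table`, `selected_name`,
#'   `selected`, per-system `slopes` of the response on log10 richness, and
#'   `mixed` (whether random intercepts were used).
#' @export
fit_bef_models <- function(data, response, richness = "S_obs",
                           system = "system", landscape = "landscape",
                           family = c("lognormal", "gaussian", "nbinom"),
                           delta_aic = 2) {
  family <- match.arg(family)
  if (length(unique(data[[system]])) < 2)
    stop("need at least two transformation systems", call. = FALSE)
  d <- data.frame(
    .y = data[[response]],
    .lr = log10(data[[richness]]),
    .system = factor(data[[system]]),
    .landscape = factor(data[[landscape]])
  )
  if (family == "lognormal") {
    if (any(d$.y <= 0))
      stop("lognormal family needs a strictly positive response", call. = FALSE)
    d$.y <- log10(d$.y)
  }
  if (any(!is.finite(d$.lr)))
    stop("richness must be positive to enter as log10(richness)", call. = FALSE)

  use_mixed <- nlevels(d$.landscape) >= 2
  random_term <- if (use_mixed) "+ (1 | .landscape)" else ""
  forms <- bef_candidates(".lr", ".system", random_term)

  fit_one <- function(f) {
    ff <- stats::as.formula(f)
    if (use_mixed) {
      # singularity is handled explicitly below; muffle lme4's boundary warning
      withCallingHandlers({
        if (family == "nbinom") lme4::glmer.nb(ff, data = d)
        else lme4::lmer(ff, data = d, REML = FALSE)
      }, warning = function(w) {
        if (grepl("boundary \\(singular\\)", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }, message = function(m) {
        if (grepl("boundary \\(singular\\)", conditionMessage(m)))
          invokeRestart("muffleMessage")
      })
    } else {
      fixed <- stats::as.formula(f)
      if (family == "nbinom") MASS::glm.nb(fixed, data = d)
      else stats::lm(fixed, data = d)
    }
  }
  models <- lapply(forms, function(f) tryCatch(fit_one(f), error = function(e) e))
  if (use_mixed) {
    degenerate <- vapply(models, function(m)
      inherits(m, "error") ||
        (inherits(m, "merMod") && lme4::isSingular(m)), logical(1))
    if (any(degenerate)) {
      # a singular/inestimable random intercept in any candidate would make
      # the AIC table incomparable: refit the whole set with fixed intercepts
      warning("random landscape intercept singular or inestimable; ",
              "falling back to fixed-intercept fits")
      use_mixed <- FALSE
      forms <- bef_candidates(".lr", ".system", "")
      models <- lapply(forms, fit_one)
    }
  }

  npar <- vapply(models, function(m) attr(logLik(m), "df"), numeric(1))
  aic <- vapply(models, AIC, numeric(1))
  aic_table <- data.frame(model = names(models), df = npar, AIC = aic,
                          dAIC = aic - min(aic), row.names = NULL)
  # backward selection with the minimum-improvement rule: among candidates
  # within delta_aic of the best AIC, take the one with fewest parameters
  contenders <- which(aic - min(aic) < delta_aic)
  selected_name <- names(models)[contenders[order(npar[contenders],
                                                  aic[contenders])][1]]
  selected <- models[[selected_name]]

  slopes <- bef_slopes(selected, selected_name, levels(d$.system))

  structure(list(models = models, aic_table = aic_table,
                 selected_name = selected_name, selected = selected,
                 slopes = slopes, family = family, mixed = use_mixed,
                 data = d, formulas = forms),
            class = "bef_fit")
}

# Per-system slope of the (possibly transformed) response on log10 richness
# under the selected model.
bef_slopes <- function(model, name, systems) {
  if (name == "null") return(setNames(rep(NA_real_, length(systems)), systems))
  fe <- if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
  base <- fe[[".lr"]]
  if (name != "full") return(setNames(rep(base, length(systems)), systems))
  out <- setNames(rep(base, length(systems)), systems)
  for (s in systems) {
    term <- paste0(".lr:.system", s)
    if (term %in% names(fe)) out[[s]] <- base + fe[[term]]
  }
  out
}

#' @export
print.bef_fit <- function(x, ...) {
  cat(sprintf("<bef_fit> family=%s, %s\n", x$family,
              if (x$mixed) "random landscape intercept" else "fixed intercept"))
  print(x$aic_table, row.names = FALSE)
  cat("selected:", x$selected_name, "\n")
  cat("per-system slopes on log10 richness:\n")
  print(round(x$slopes, 4))
  invisible(x)
}

#' Moran's I test on model residuals
#'
#' Computes Moran's I,
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' residuals and `S0` the sum of weights, under row-standardized
#' k-nearest-neighbour binary weights built from site coordinates, and tests
#' it against its null expectation `-1/(n-1)` with the normal-approximation
#' standard deviate (two-sided by default).
#'
#' @param residuals Numeric vector of model residuals.
#' @param coords Two-column matrix or data frame of site coordinates.
#' @param k Number of nearest neighbours (default 4).
#' @param alternative Passed to the normal test: "two.sided", "greater",
#'   "less".
#' @return List: `I`, `expected`, `sd`, `p`, `defined` (FALSE with all-NA
#'   statistics when residuals have zero variance), and the weight matrix.
#' @export
morans_i <- function(residuals, coords, k = 4, alternative = "two.sided") {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 3 || nrow(coords) != n)
    stop("need >= 3 residuals with matching coordinates", call. = FALSE)
  W <- knn_weights(coords, k)
  if (sd(residuals) == 0) {
    warning("Moran's I undefined: residuals have zero variance")
    return(list(I = NA_real_, expected = -1 / (n - 1), sd = NA_real_,
                p = NA_real_, defined = FALSE, weights = W))
  }
  res <- ape::Moran.I(residuals, W, scaled = FALSE, alternative = alternative)
  list(I = res$observed, expected = res$expected, sd = res$sd,
       p = res$p.value, defined = TRUE, weights = W)
}

# Row-standardized binary k-nearest-neighbour weights. Ties in distance are
# broken by index order for determinism.
knn_weights <- function(coords, k = 4) {
  n <- nrow(coords)
  if (k >= n) k <- n - 1
  D <- as.matrix(dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    idx <- seq_len(n)[-i][nb]
    W[i, idx] <- 1 / k
  }
  W
}

#' @importFrom stats dist
NULL
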