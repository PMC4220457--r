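#' Observed species richness
#'
#' @param x A `site_community` or a character vector of species ids.
#' @return Number of distinct species with at least one individual.
#' @export
observed_richness <- function(x) {
  ids <- if (inherits(x, "site_community")) x$individuals$species_id else x
  length(unique(ids))
}

#' Subplot incidence table of a site
#'
#' Presence/absence of every observed species in each of the site's m
#' subsamples, with the singleton/doubleton incidence counts used by the
#' second-order jackknife: Q1 = species found in exactly one subsample,
#' Q2 = in exactly two.
#'
#' @param site A `site_community`.
#' @return List with the m x S logical `incidence` matrix, `Q1`, `Q2`,
#'   `S_obs`, `m` and the pooled per-species abundance vector `abundance`.
#' @export
incidence_table <- function(site) {
  ind <- site$individuals
  m <- site$n_subplots
  species <- sort(unique(ind$species_id))
  inc <- matrix(FALSE, nrow = m, ncol = length(species),
                dimnames = list(paste0("subplot", seq_len(m)), species))
  if (nrow(ind)) {
    pres <- unique(ind[, c("subplot", "species_id")])
    inc[cbind(pres$subplot, match(pres$species_id, species))] <- TRUE
  }
  freq <- colSums(inc)
  abundance <- if (nrow(ind)) as.vector(table(ind$species_id)[species]) else integer()
  list(incidence = inc, Q1 = sum(freq == 1), Q2 = sum(freq == 2),
       S_obs = length(species), m = m,
       abundance = setNames(abundance, species))
}

#' Second-order jackknife richness estimator
#'
#' Nonparametric extrapolation of species richness from incidence across m
#' subsamples: `S_jack2 = S_obs + Q1 (2m - 3) / m - Q2 (m - 2)^2 / (m (m - 1))`.
#' With m = 3 subsamples this reduces to `S_obs + Q1 - Q2 / 6`.
#'
#' @param x A `site_community`, an [incidence_table()] list, or a logical /
#'   0-1 incidence matrix (subsamples in rows, species in columns).
#' @return The extrapolated richness estimate.
#' @export
#' @examples
#' jackknife2(matrix(c(1,0,0, 1,1,0, 1,1,1), nrow = 3))
jackknife2 <- function(x) {
  if (inherits(x, "site_community")) x <- incidence_table(x)
  if (is.matrix(x)) {
    freq <- colSums(x > 0)
    freq <- freq[freq > 0]
    x <- list(Q1 = sum(freq == 1), Q2 = sum(freq == 2),
              S_obs = length(freq), m = nrow(x))
  }
  m <- x$m
  if (m < 3)
    stop("second-order jackknife needs at least 3 subsamples", call. = FALSE)
  x$S_obs + x$Q1 * (2 * m - 3) / m - x$Q2 * (m - 2)^2 / (m * (m - 1))
}

#' Individual-based rarefied richness
#'
#' Expected number of species in a random draw of n individuals from the
#' pooled site sample (hypergeometric expectation,
#' `E[S_n] = sum_i 1 - choose(N - N_i, n) / choose(N, n)`), evaluated through
#' `vegan::rarefy`, which computes the combinatorial terms in log space.
#'
#' @param abundances Per-species abundance vector (nonnegative integers).
#' @param n Number of individuals to rarefy to (1 <= n <= sum(abundances)).
#' @return Expected species richness at sample size n.
#' @export
#' @examples
#' rarefy_richness(c(5, 5), 2)  # 14/9
rarefy_richness <- function(abundances, n) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  if (n < 1) stop("rarefaction sample size must be >= 1", call. = FALSE)
  if (n > N)
    stop(sprintf("cannot rarefy to %d individuals from a sample of %d", n, N),
         call. = FALSE)
  # vegan warns when no species is a singleton; harmless for the expectation
  withCallingHandlers(
    as.numeric(vegan::rarefy(matrix(abundances, nrow = 1), sample = n)),
    warning = function(w) {
      if (grepl("most observed count data", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Per-site diversity summary
#'
#' Observed richness, second-order jackknife extrapolation, sampling coverage
#' (S_obs / S_jack2) and richness rarefied to `rarefy_n` individuals (or to
#' the site total when fewer were collected).
#'
#' @param site A `site_community`.
#' @param rarefy_n Rarefaction cut-off in individuals (default 40, the
#'   smallest site sample the design anticipates).
#' @return One-row data frame: S_obs, S_jack2, coverage, S_rarefied, n_individuals.
#' @export
site_diversity <- function(site, rarefy_n = 40) {
  tab <- incidence_table(site)
  n_ind <- sum(tab$abundance)
  s_jack <- if (tab$m >= 3) jackknife2(tab) else NA_real_
  s_rare <- if (n_ind >= 1) rarefy_richness(tab$abundance, min(rarefy_n, n_ind))
            else NA_real_
  data.frame(S_obs = tab$S_obs, S_jack2 = s_jack,
             coverage = if (!is.na(s_jack) && s_jack > 0) tab$S_obs / s_jack else NA_real_,
             S_rarefied = s_rare, n_individuals = n_ind)
}

#' Sampling-coverage summary across sites
#'
#' Per-site coverage (S_obs / S_jack2) with its mean and standard deviation,
#' and the Pearson correlation of observed and extrapolated richness across
#' sites (flagged undefined when either vector has zero variance).
#'
#' @param diversity Data frame with columns S_obs and S_jack2 (e.g. stacked
#'   [site_diversity()] rows).
#' @return List: per-site `coverage`, `mean_coverage`, `sd_coverage`,
#'   `pearson_r` (NA when undefined) and `pearson_defined`.
#' @export
coverage_summary <- function(diversity) {
  stopifnot(all(c("S_obs", "S_jack2") %in% names(diversity)))
  if (nrow(diversity) < 3)
    stop("coverage summary needs at least 3 sites", call. = FALSE)
  cov <- diversity$S_obs / diversity$S_jack2
  defined <- sd(diversity$S_obs) > 0 && sd(diversity$S_jack2) > 0
  r <- if (defined) cor(diversity$S_obs, diversity$S_jack2) else NA_real_
  if (!defined)
    warning("Pearson correlation undefined: zero variance in richness vector(s)")
  list(coverage = cov, mean_coverage = mean(cov), sd_coverage = sd(cov),
       pearson_r = r, pearson_defined = defined)
}
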