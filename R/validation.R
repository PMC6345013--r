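# Growth-phenotype validation: sole-source growth tests, agreement scoring
# and growth-rate deviation statistics.

#' Sole carbon/nitrogen source growth test
#'
#' For each substrate, opens only that substrate's exchange among the
#' sources of the tested role at the given uptake rate (all other listed
#' sources closed), solves FBA on the growth objective, and records a
#' predicted growth call: `"+"` iff the optimal growth exceeds the
#' growth-call threshold. Substrates without a mapped exchange reaction are
#' recorded as untestable rather than silently skipped.
#'
#' @param model A `metabolic_model`.
#' @param substrates A data frame with columns `substrate`, `exchange`
#'   (exchange reaction id or `NA`) and optionally `observed` (`"+"`/`"-"`).
#' @param role `"carbon"` or `"nitrogen"` (recorded on the output).
#' @param uptake Uptake rate for the tested substrate (mmol/gDW/h).
#' @param base_medium Named uptake vector (see [set_medium()]) supplying
#'   everything except the varied sources; typically a minimal medium with
#'   the role's default source removed.
#' @param unlimited Exchanges left unconstrained (ions, water, protons...).
#' @param threshold Growth-call threshold on the objective (1/h); the same
#'   value should be used here and in deletion screens.
#' @return A tibble of `PhenotypeRecord`s: `substrate`, `role`, `exchange`,
#'   `observed`, `predicted`, `growth`, `untestable`.
#' @export
sole_source_growth_test <- function(model, substrates, role = "carbon",
                                    uptake = 2.0, base_medium = NULL,
                                    unlimited = NULL, threshold = 1e-6) {
  substrates <- tibble::as_tibble(substrates)
  if (!("observed" %in% names(substrates))) substrates$observed <- NA_character_
  role_ex <- substrates$exchange[!is.na(substrates$exchange)]
  base <- base_medium %||na% numeric(0)
  base <- base[setdiff(names(base), role_ex)]  # close every varied source
  one <- function(i) {
    ex <- substrates$exchange[i]
    if (is.na(ex) || !(ex %in% model$reactions$id)) {
      return(tibble::tibble(
        substrate = substrates$substrate[i], role = role, exchange = ex,
        observed = substrates$observed[i], predicted = NA_character_,
        growth = NA_real_, untestable = TRUE))
    }
    med <- c(base, stats::setNames(uptake, ex))
    sol <- solve_fba(set_medium(model, med, unlimited = unlimited))
    growth <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(
      substrate = substrates$substrate[i], role = role, exchange = ex,
      observed = substrates$observed[i],
      predicted = if (growth > threshold) "+" else "-",
      growth = growth, untestable = FALSE)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(substrates)), one))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Score observed/predicted phenotype agreement
#'
#' Counts matching growth calls and reports the agreement percentage,
#' rounded half-up to the nearest integer for reporting (11/12 prints as
#' 92%); the raw fraction is retained. Permutation-invariant.
#'
#' @param records A data frame with columns `observed` and `predicted`
#'   (`"+"`/`"-"`); rows with a missing call are excluded from the total.
#' @return A one-row tibble: `matches`, `total`, `percent` (integer,
#'   half-up), `percent_raw`.
#' @examples
#' agreement_score(dplyr::filter(growth_phenotype_fixture(), role == "carbon"))
#' @export
agreement_score <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no phenotype records to score")
  ok <- !is.na(records$observed) & !is.na(records$predicted)
  matches <- sum(records$observed[ok] == records$predicted[ok])
  total <- sum(ok)
  if (total == 0) stop("no scorable phenotype records (all calls missing)")
  raw <- 100 * matches / total
  tibble::tibble(matches = matches, total = total,
                 percent = round_half_up(raw), percent_raw = raw)
}

#' Relative deviation between predicted and observed rates
#'
#' `100 * |predicted - observed| / denominator`, with the denominator taken
#' from the observed (in vivo) or predicted (in silico) rate.
#'
#' @param predicted,observed Rates (e.g. growth rates in 1/h); vectorized.
#' @param denominator `"observed"` (default) or `"predicted"`.
#' @return Percent deviation(s).
#' @examples
#' relative_deviation(0.1247, 0.1104)  # 12.95...
#' relative_deviation(0.1013, 0.1000)  # 1.3
#' @export
relative_deviation <- function(predicted, observed,
                               denominator = c("observed", "predicted")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "observed") observed else predicted
  if (any(den == 0)) stop("zero denominator in relative deviation")
  100 * abs(predicted - observed) / abs(den)
}

#' Share of protein-coding genes captured by a model
#'
#' @param n_model_genes Genes in the metabolic model.
#' @param n_genome_genes Predicted protein-coding genes in the genome.
#' @return Percent coverage.
#' @examples
#' gene_coverage(1539, 13606)  # 11.31...
#' @export
gene_coverage <- function(n_model_genes, n_genome_genes) {
  if (n_genome_genes <= 0) stop("genome gene count must be positive")
  100 * n_model_genes / n_genome_genes
}
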