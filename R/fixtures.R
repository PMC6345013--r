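# Deterministic tabular fixtures: ortholog hit tables and the published
# growth-phenotype / growth-rate validation tables.

#' Generate a synthetic ortholog hit table
#'
#' Produces exactly `n_pass` BLAST-like hits satisfying the draft-model
#' thresholds (identity >= 40%, e-value <= 1e-30) and `n_fail` hits
#' violating at least one of them (low identity, high e-value, or both,
#' cycled deterministically), shuffled by `seed`. The same seed always
#' yields the identical table.
#'
#' @param seed Integer seed.
#' @param n_pass,n_fail Row counts (>= 0).
#' @param reference Reference-model label(s), recycled over rows.
#' @return A tibble with columns `query`, `subject`, `identity`, `evalue`,
#'   `reference`, `passes` (construction flag).
#' @examples
#' hits <- generate_ortholog_hits(seed = 1, n_pass = 37, n_fail = 63)
#' nrow(filter_orthologs(hits))  # 37
#' @export
generate_ortholog_hits <- function(seed, n_pass, n_fail,
                                   reference = c("iJL1454", "iRA1006",
                                                 "iTO977")) {
  stopifnot(n_pass >= 0, n_fail >= 0)
  withr::with_seed(seed, {
    n <- n_pass + n_fail
    if (n == 0) {
      return(tibble::tibble(query = character(0), subject = character(0),
                            identity = numeric(0), evalue = numeric(0),
                            reference = character(0), passes = logical(0)))
    }
    pass <- tibble::tibble(
      identity = round(stats::runif(n_pass, 40, 98), 1),
      evalue = 10^stats::runif(n_pass, -180, -30),
      passes = rep(TRUE, n_pass)
    )
    mode <- rep_len(c("identity", "evalue", "both"), n_fail)
    fail <- tibble::tibble(
      identity = ifelse(mode %in% c("identity", "both"),
                        round(stats::runif(n_fail, 5, 39.9), 1),
                        round(stats::runif(n_fail, 40, 98), 1)),
      evalue = ifelse(mode %in% c("evalue", "both"),
                      10^stats::runif(n_fail, -29, -1),
                      10^stats::runif(n_fail, -180, -30)),
      passes = rep(FALSE, n_fail)
    )
    out <- dplyr::bind_rows(pass, fail)
    out$query <- sprintf("Gglean%06d.1", seq_len(n))
    out$subject <- sprintf("REFG%04d", seq_len(n))
    out$reference <- rep_len(reference, n)
    out <- out[sample.int(n), c("query", "subject", "identity", "evalue",
                                "reference", "passes")]
    tibble::as_tibble(out)
  })
}

#' Published growth-phenotype validation table
#'
#' Transcription of the qualitative validation of the genome-scale model:
#' 20 sole carbon sources and 12 sole nitrogen sources with observed
#' (in vivo) and model-predicted (in silico) growth calls. Substrates
#' marked `gapfilled` grew in silico only after gap filling.
#'
#' @return A tibble with columns `substrate`, `role`, `observed`,
#'   `predicted`, `gapfilled`.
#' @examples
#' agreement_score(dplyr::filter(growth_phenotype_fixture(), role == "carbon"))
#' @export
growth_phenotype_fixture <- function() {
  carbon <- tibble::tribble(
    ~substrate, ~observed, ~predicted, ~gapfilled,
    "Glucose", "+", "+", FALSE,
    "Fructose", "+", "+", FALSE,
    "Galactose", "+", "+", FALSE,
    "Lactose", "+", "+", FALSE,
    "Maltose", "+", "+", FALSE,
    "Mannose", "+", "+", FALSE,
    "Pectin", "+", "-", FALSE,
    "Ribose", "+", "+", FALSE,
    "Starch", "+", "+", TRUE,
    "Sucrose", "+", "+", TRUE,
    "Xylose", "+", "+", FALSE,
    "Arabinose", "+", "+", FALSE,
    "Rhamnose", "+", "+", TRUE,
    "Raffinose", "+", "+", FALSE,
    "Glycerol", "+", "+", FALSE,
    "Dextrin", "+", "+", TRUE,
    "Citrate", "+", "-", FALSE,
    "Polygalacturonic acid", "+", "-", FALSE,
    "Cellobiose", "+", "+", FALSE,
    "Sorbose", "+", "+", FALSE
  )
  nitrogen <- tibble::tribble(
    ~substrate, ~observed, ~predicted, ~gapfilled,
    "NH4Cl", "+", "+", FALSE,
    "KNO3", "+", "+", FALSE,
    "NaNO2", "+", "+", FALSE,
    "Acetamide", "+", "-", FALSE,
    "Urea", "+", "+", FALSE,
    "Glycine", "+", "+", FALSE,
    "Glutamate", "+", "+", FALSE,
    "Arginine", "+", "+", FALSE,
    "Alanine", "+", "+", FALSE,
    "Aspartate", "+", "+", FALSE,
    "Asparagine", "+", "+", FALSE,
    "Tyrosine", "+", "+", FALSE
  )
  dplyr::bind_rows(
    dplyr::mutate(carbon, role = "carbon", .after = "substrate"),
    dplyr::mutate(nitrogen, role = "nitrogen", .after = "substrate")
  )
}

#' Published quantitative growth-rate validation values
#'
#' Observed (in vivo) versus predicted (in silico) specific growth rates:
#' defined-uptake glucose and sucrose cultures, and the minimal-medium
#' prediction at glucose 2.0 mmol/gDW/h compared against the
#' literature-derived rate.
#'
#' @return A tibble with columns `condition`, `uptake` (mmol/gDW/h),
#'   `observed`, `predicted` (1/h).
#' @examples
#' with(growth_rate_fixture(), relative_deviation(predicted, observed))
#' @export
growth_rate_fixture <- function() {
  tibble::tribble(
    ~condition, ~uptake, ~observed, ~predicted,
    "glucose", 1.65, 0.1000, 0.1013,
    "sucrose", 0.73, 0.0893, 0.0885,
    "minimal glucose 2.0", 2.00, 0.1104, 0.1247
  )
}
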