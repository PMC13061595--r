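#' Default expected risk directions for the fitness traits
#'
#' BMI is expected to be risk-increasing (+1); aerobic capacity, strength,
#' power and cognition are expected protective (-1). Used by
#' [assess_direction_consistency()] when net signs are compared to prior
#' expectation.
#'
#' @return Named numeric vector of +1 / -1 per trait.
#' @export
default_expected_directions <- function() {
  c(vo2max = -1, grip_strength = -1, jump_max = -1, bmi = +1, cognition = -1)
}

#' Link significant fitness-EpiScore associations to disease hazards
#'
#' Inner join of the significant association rows with the external
#' EpiScore-disease hazard table on `protein_id`, giving one row per
#' (trait, protein, disease) triple. The chain's net direction is
#' `net_sign = sign(beta) * sign(log_hr)`: the sign of the fitness effect
#' propagated through the published hazard.
#'
#' @param sig Data frame of significant association rows (needs
#'   `fitness_trait`, `protein_id`, `beta`).
#' @param hazards Data frame with `disease`, `protein_id`, `log_hr`.
#' @return Data frame with columns `fitness_trait`, `protein_id`, `disease`,
#'   `beta`, `log_hr`, `net_sign`, `zero_product`; empty (with a warning) if
#'   the join is empty.
#' @export
link_fitness_disease <- function(sig, hazards) {
  if (anyDuplicated(hazards[c("disease", "protein_id")]))
    stop("link_fitness_disease: (disease, protein) pairs must be unique",
         call. = FALSE)
  links <- merge(sig[c("fitness_trait", "protein_id", "beta")],
                 hazards[c("disease", "protein_id", "log_hr")],
                 by = "protein_id")
  links <- links[c("fitness_trait", "protein_id", "disease",
                   "beta", "log_hr")]
  links <- links[order(links$fitness_trait, links$protein_id, links$disease), ]
  rownames(links) <- NULL
  links$net_sign <- sign(links$beta) * sign(links$log_hr)
  links$zero_product <- links$net_sign == 0
  if (nrow(links) == 0L)
    warning("link_fitness_disease: no protein overlaps between the ",
            "significant associations and the hazard table", call. = FALSE)
  else if (any(links$zero_product))
    warning("link_fitness_disease: ", sum(links$zero_product),
            " link(s) with a zero coefficient product", call. = FALSE)
  links
}

#' Assess direction consistency of fitness-disease links
#'
#' A link is consistent when its net sign (fitness -> EpiScore coefficient
#' sign times log-hazard sign) equals the a priori expected risk direction of
#' its fitness trait. Links with a zero net sign count as inconsistent and
#' stay flagged. Both the triple-level count and the (trait, disease)
#' pair-level count are reported, since "one association" can be read at
#' either granularity when several proteins connect the same pair.
#'
#' @param links Link table from [link_fitness_disease()].
#' @param expected Named vector of expected directions per trait (+1 / -1);
#'   default [default_expected_directions()].
#' @return List with `links` (input plus `expected_sign`, `consistent`),
#'   `consistent_count`, `n_links`, and `pair_counts` (data frame of distinct
#'   (trait, disease) pairs with `any_consistent`).
#' @export
assess_direction_consistency <- function(links,
                                         expected = default_expected_directions()) {
  miss <- setdiff(unique(links$fitness_trait), names(expected))
  if (length(miss))
    stop("assess_direction_consistency: no expected direction for trait(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  links$expected_sign <- unname(expected[links$fitness_trait])
  links$consistent <- links$net_sign == links$expected_sign &
    links$net_sign != 0
  pairs <- unique(links[c("fitness_trait", "disease")])
  pairs$any_consistent <- mapply(function(tr, d) {
    any(links$consistent[links$fitness_trait == tr & links$disease == d])
  }, pairs$fitness_trait, pairs$disease)
  rownames(pairs) <- NULL
  list(links = links,
       consistent_count = sum(links$consistent),
       n_links = nrow(links),
       pair_counts = pairs)
}
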