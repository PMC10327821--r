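#' Treatment-allocation decision tree
#'
#' Each stratum enters a short decision tree that allocates patients to
#' endocrine therapy alone (ET) or endocrine therapy plus chemotherapy
#' (ET_CT). Under the genomic-test strategy (ODX) allocation is stratified by
#' recurrence-score category, each category carrying its own probability of
#' receiving chemotherapy; under standard of care (SOC) a single
#' stratum-level chemotherapy probability applies. Every leaf of the tree is
#' a homogeneous branch cohort that is propagated separately through the
#' Markov stage and weight-averaged afterwards.
#'
#' @name decision_tree
NULL

#' Normalized recurrence-score shares for a stratum
#'
#' The published premenopausal shares (33.7% / 73.9% / 27.1%) cannot sum to
#' one; the outer categories are taken as authoritative and the middle share
#' is derived as their complement (39.2%). Postmenopausal strata (low
#' category share 0) pass through unchanged.
#'
#' @param spec A subpopulation spec from a model configuration.
#' @return list with `lt16`, `mid`, `gt25` summing to 1.
#' @export
effective_rs_shares <- function(spec) {
  sh <- spec$rs_shares
  lt16 <- as.numeric(sh$lt16)
  gt25 <- as.numeric(sh$gt25)
  mid <- if (lt16 > 0) 1 - lt16 - gt25 else as.numeric(sh$mid)
  out <- list(lt16 = lt16, mid = mid, gt25 = gt25)
  if (any(unlist(out) < 0) || any(unlist(out) > 1)) {
    stop("validation error: rs_shares outside [0,1] after normalization")
  }
  out
}

#' Branch cohorts for one stratum under one strategy
#'
#' @param spec A subpopulation spec.
#' @param strategy `"ODX"` or `"SOC"`.
#' @return data.frame of branches with columns `stratum_id`, `strategy`,
#'   `rs_context` (`rs_lt16` / `rs_mid` / `rs_gt25` / `soc`), `treatment`
#'   (`ET` / `ET_CT`) and `weight`; zero-weight branches are dropped and
#'   weights sum to 1.
#' @export
branch_weights <- function(spec, strategy = c("ODX", "SOC")) {
  strategy <- match.arg(strategy)
  if (strategy == "SOC") {
    q <- as.numeric(spec$soc_ct_prob)
    br <- data.frame(
      stratum_id = spec$id, strategy = strategy, rs_context = "soc",
      treatment = c("ET_CT", "ET"), weight = c(q, 1 - q),
      stringsAsFactors = FALSE)
  } else {
    sh <- effective_rs_shares(spec)
    ctx <- c(lt16 = "rs_lt16", mid = "rs_mid", gt25 = "rs_gt25")
    rows <- lapply(names(ctx), function(cat) {
      s <- sh[[cat]]
      q <- as.numeric(spec$ct_prob_by_rs[[cat]])
      if (is.null(q) || is.na(q)) q <- 0
      data.frame(
        stratum_id = spec$id, strategy = strategy, rs_context = ctx[[cat]],
        treatment = c("ET_CT", "ET"), weight = c(s * q, s * (1 - q)),
        stringsAsFactors = FALSE)
    })
    br <- do.call(rbind, rows)
  }
  br <- br[br$weight > 0, , drop = FALSE]
  rownames(br) <- NULL
  stopifnot(abs(sum(br$weight) - 1) < 1e-9)
  br
}

#' Strategy-level chemotherapy probability for a stratum
#'
#' @inheritParams branch_weights
#' @return Sum of ET_CT branch weights.
#' @export
ct_probability <- function(spec, strategy = c("ODX", "SOC")) {
  strategy <- match.arg(strategy)
  br <- branch_weights(spec, strategy)
  sum(br$weight[br$treatment == "ET_CT"])
}
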