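# Flow-cytometry gating tree for T-cell residency phenotyping.
#
# Gate order: viability -> lymphocyte -> CD3 -> {CD4, CD8} -> residency
# (CD69/CD103) -> CD39 -> PD-1. Residency classes for CD8 events are
# DN (CD69-CD103-, circulating), SP (CD69+CD103-, intermediate) and
# DP (CD69+CD103+, tumor-resident); CD69-CD103+ events do not belong to any
# of the three classes and are excluded (reported separately), not pooled.

FLOW_MARKERS <- c("viability", "scatter", "CD3", "CD4", "CD8",
                  "CD69", "CD103", "CD39", "PD1")

#' Define the gating tree
#'
#' Each gate keeps events at or above its marker threshold, except the
#' viability gate, which keeps events below it (the viability dye marks
#' dead cells). Default thresholds sit at the antimode of the bimodal
#' lognormal intensity model.
#'
#' @param thresholds named numeric vector of per-marker gate thresholds
#' @return an object of class `gating_tree`
#' @export
gating_tree <- function(thresholds = setNames(rep(exp(2.5), length(FLOW_MARKERS)),
                                              FLOW_MARKERS)) {
  missing_m <- setdiff(FLOW_MARKERS, names(thresholds))
  assert_that(length(missing_m) == 0,
              sprintf("gating tree missing threshold(s): %s",
                      paste(missing_m, collapse = ", ")))
  structure(list(thresholds = thresholds), class = "gating_tree")
}

pct_of <- function(k, n) if (n == 0) NA_real_ else 100 * k / n

#' Apply the gating tree to a flow-cytometry event table
#'
#' Fractions are reported per node as percentages of the parent gate:
#' CD4 and CD8 of lymphocytes; DN/SP/DP (and excluded CD69-CD103+) of CD8;
#' CD39+ of CD8 overall and within each residency class; PD-1+ within each
#' CD39-by-residency cell; CD69+ of CD4. A parent gate with zero events
#' yields `NA` (missing) child fractions, never 0.
#'
#' @param events data.frame with one column per gated marker
#' @param tree a [gating_tree()]
#' @return nested list of gate fractions (percent) and event counts
#' @export
gate_flow <- function(events, tree = gating_tree()) {
  missing_m <- setdiff(FLOW_MARKERS, names(events))
  assert_that(length(missing_m) == 0,
              sprintf("event table missing marker(s): %s",
                      paste(missing_m, collapse = ", ")))
  th <- tree$thresholds
  pos <- function(m) events[[m]] >= th[[m]]
  live <- !pos("viability")
  lymph <- live & pos("scatter")
  t_cells <- lymph & pos("CD3")
  cd4 <- t_cells & pos("CD4") & !pos("CD8")
  cd8 <- t_cells & pos("CD8") & !pos("CD4")
  cd69 <- pos("CD69"); cd103 <- pos("CD103")
  res <- list(DN = cd8 & !cd69 & !cd103,
              SP = cd8 & cd69 & !cd103,
              DP = cd8 & cd69 & cd103,
              excluded = cd8 & !cd69 & cd103)
  cd39 <- pos("CD39"); pd1 <- pos("PD1")
  n_lymph <- sum(lymph); n_cd8 <- sum(cd8); n_cd4 <- sum(cd4)

  residency_pct <- lapply(res, function(idx) pct_of(sum(idx), n_cd8))
  cd39_by_res <- lapply(res[c("DN", "SP", "DP")], function(idx) {
    pct_of(sum(idx & cd39), sum(idx))
  })
  pd1_by <- list()
  for (r in c("DN", "SP", "DP")) {
    for (c39 in c(TRUE, FALSE)) {
      parent <- res[[r]] & (cd39 == c39)
      key <- sprintf("%s_%s", if (c39) "CD39pos" else "CD39neg", r)
      pd1_by[[key]] <- pct_of(sum(parent & pd1), sum(parent))
    }
  }
  list(
    n_events = nrow(events),
    n_lymphocytes = n_lymph,
    pct_cd4_of_lymph = pct_of(n_cd4, n_lymph),
    pct_cd8_of_lymph = pct_of(n_cd8, n_lymph),
    n_cd8 = n_cd8,
    residency = residency_pct,
    pct_cd39_of_cd8 = pct_of(sum(cd8 & cd39), n_cd8),
    pct_cd39_by_residency = cd39_by_res,
    pct_pd1_by_cd39_residency = pd1_by,
    pct_cd69_of_cd4 = pct_of(sum(cd4 & cd69), n_cd4)
  )
}
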