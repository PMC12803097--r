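#' Worked-example summary tables from a global marine analysis
#'
#' Small plain-text tables bundled with the package: the published summary
#' output of a global ancestral-range analysis of four marine groups
#' (cetaceans, seagrasses, reef-forming corals, ray-finned fishes) across the
#' nine marine realms.  They serve as worked-example inputs for the
#' downstream accounting functions without re-running any model:
#'
#' * `process_totals` — global mean event counts per process type with the
#'   published percentages;
#' * `realm_rates` — per-group, per-realm richness-standardized emigration,
#'   immigration, extinction and in-situ speciation rates;
#' * `interchange` — per-group 9 x 9 dispersal matrices (source realms in
#'   rows, sink realms in columns, diagonal zero).
#'
#' @return list with elements `process_totals` (data.frame), `realm_rates`
#'   (data.frame) and `interchange` (named list of matrices).
#' @examples
#' tabs <- example_tables()
#' process_shares(stats::setNames(tabs$process_totals$total_events,
#'                                tabs$process_totals$process_type))
#' @export
example_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "searange", mustWork = TRUE)
  inter <- lapply(c(corals = "interchange_corals.tsv",
                    cetaceans = "interchange_cetaceans.tsv",
                    seagrasses = "interchange_seagrasses.tsv",
                    fishes = "interchange_fishes.tsv"), function(f) {
    df <- utils::read.delim(path(f), check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$source
    m
  })
  list(process_totals = utils::read.delim(path("global_process_totals.tsv")),
       realm_rates = utils::read.delim(path("realm_event_rates.tsv")),
       interchange = inter)
}
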