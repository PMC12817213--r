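#' Read and validate a species-level prevalence table
#'
#' Reads a CSV with one row per species.  Required columns: `species`,
#' `n_records`, plus either `n_event` or `prevalence`.  When counts are
#' present, prevalence and its sampling SE are derived via
#' [prevalence_se()]; tables supplying only `prevalence` are accepted but
#' the binomial GEE will later refuse them (it needs counts).  Extra
#' columns (e.g. continuous life-history predictors) are kept.
#'
#' @param path path to a CSV file with a header row.
#' @return a validated data.frame of species records.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "n_records")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  if (is.null(tab$n_event) && is.null(tab$prevalence))
    stopf("table needs either an n_event or a prevalence column")

  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      stopf("%s in row(s): %s", what,
            paste(which(cond | is.na(cond)), collapse = ", "))
  }
  bad_row(tab$n_records < 1 | tab$n_records != round(tab$n_records),
          "n_records must be a positive integer")
  if (!is.null(tab$n_event))
    bad_row(tab$n_event < 0 | tab$n_event > tab$n_records,
            "n_event outside [0, n_records]")
  if (!is.null(tab$prevalence))
    bad_row(tab$prevalence < 0 | tab$prevalence > 1,
            "prevalence outside [0, 1]")

  if (anyDuplicated(tab$species)) {
    dup <- unique(tab$species[duplicated(tab$species)])
    keyed <- tab[tab$species %in% dup, , drop = FALSE]
    conflicting <- vapply(split(keyed, keyed$species),
                          function(g) nrow(unique(g)) > 1, logical(1))
    if (any(conflicting))
      stopf("conflicting duplicate rows for species: %s",
            paste(names(conflicting)[conflicting], collapse = ", "))
    tab <- tab[!duplicated(tab$species), , drop = FALSE]
  }

  if (!is.null(tab$n_event)) {
    ps <- prevalence_se(tab$n_event, tab$n_records)
    if (is.null(tab$prevalence)) tab$prevalence <- ps$prevalence
    if (is.null(tab$se)) tab$se <- ps$se
  }
  rownames(tab) <- NULL
  tab
}
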