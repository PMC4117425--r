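# Validation harness over published benchmark tables, shipped as packaged
# TSV fixtures: the protein-protein interaction set with per-structure
# rigid/flexible scores and volumes, and the flexible-pocket comparison set
# with per-structure scores for a docking-based method and the flexibility
# method. Scores in these tables are printed inputs, not recomputed values.

#' Load the packaged protein-protein interaction validation table
#' @return data frame: target, pdb_id, ligand_type, assigned_druggability,
#'   rigid/flexible Dscore+ and volumes (NA where flexibility modeling was
#'   not applied)
#' @export
load_ppi_table <- function() {
  utils::read.delim(system.file("extdata", "ppi_validation_set.tsv",
                                package = "flexsite"),
                    stringsAsFactors = FALSE)
}

#' Load the packaged flexible-pocket score comparison table
#' @return data frame: target, ppi flag, method (docking/flexible), pdb_id,
#'   score
#' @export
load_flex_table <- function() {
  utils::read.delim(system.file("extdata", "flexible_pocket_scores.tsv",
                                package = "flexsite"),
                    stringsAsFactors = FALSE)
}

# round half up on non-negative percentages
round_pct <- function(x) floor(x + 0.5)

#' False-positive and false-negative rates on a validation table
#'
#' A row is predicted positive when its flexible-model Dscore+ passes the
#' flexible gate and its flexible volume lies in the drug-like range; rows
#' without flexible values are predicted negative. FP% is the fraction of
#' predicted positives whose assigned druggability is difficult; FN% the
#' fraction of assigned-druggable rows predicted negative. Both rounded to
#' whole percent.
#'
#' @param rows data frame in [load_ppi_table()] layout
#' @param cfg [decision_config()]
#' @return named numeric: `fp_percent`, `fn_percent`
#' @export
fp_fn_rates <- function(rows = load_ppi_table(), cfg = decision_config()) {
  positive <- !is.na(rows$flex_dscore_plus) & !is.na(rows$flex_volume) &
    rows$flex_dscore_plus >= cfg$flexible_gate &
    rows$flex_volume >= cfg$druglike_volume[1] &
    rows$flex_volume <= cfg$druglike_volume[2]
  druggable <- rows$assigned_druggability == "druggable"
  fp <- if (any(positive)) 100 * sum(positive & !druggable) / sum(positive) else 0
  fn <- if (any(druggable)) 100 * sum(druggable & !positive) / sum(druggable) else 0
  c(fp_percent = round_pct(fp), fn_percent = round_pct(fn))
}

#' Variation statistic of a score list
#'
#' (max - min) / mean, as a whole percent: the spread of a target's
#' druggability scores across its crystal structures.
#'
#' @param scores numeric vector (at least 2 finite values)
#' @return whole-number percent
#' @export
variation <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) stop("variation needs at least 2 finite scores")
  round_pct((max(scores) - min(scores)) / mean(scores) * 100)
}

#' Per-target variation for one method column
#'
#' @param tab data frame in [load_flex_table()] layout
#' @param method `"docking"` or `"flexible"`
#' @return named numeric vector of per-target variation percents, in table
#'   order
#' @export
variation_by_target <- function(tab = load_flex_table(), method = "flexible") {
  sub <- tab[tab$method == method, , drop = FALSE]
  targets <- unique(sub$target)
  setNames(vapply(targets, function(t) variation(sub$score[sub$target == t]),
                  numeric(1)), targets)
}

#' Median and spread of per-target variations
#'
#' @param variations numeric vector of (rounded) per-target variations
#' @return named numeric: `median_percent`, `sd_percent` (sample, n-1
#'   standard deviation), each rounded to whole percent
#' @export
variation_summary <- function(variations) {
  c(median_percent = round_pct(stats::median(variations)),
    sd_percent = round_pct(stats::sd(variations)))
}

#' Print the validation comparison report
#'
#' Recomputes the variation statistics and FP/FN rates from the packaged
#' tables and prints them.
#'
#' @param cfg [decision_config()]
#' @return invisibly, a list with all computed values
#' @export
validate_benchmark_tables <- function(cfg = decision_config()) {
  rates <- fp_fn_rates(load_ppi_table(), cfg)
  tab <- load_flex_table()
  v_dock <- variation_by_target(tab, "docking")
  v_flex <- variation_by_target(tab, "flexible")
  s_dock <- variation_summary(v_dock)
  s_flex <- variation_summary(v_flex)
  cat("PPI validation set:\n")
  cat(sprintf("  false positives: %d%%   false negatives: %d%%\n",
              rates[["fp_percent"]], rates[["fn_percent"]]))
  cat("Score variation across structures of the same target:\n")
  cat(sprintf("  docking method:     median %d%%, sd %d%%\n",
              s_dock[["median_percent"]], s_dock[["sd_percent"]]))
  cat(sprintf("  flexibility method: median %d%%, sd %d%%\n",
              s_flex[["median_percent"]], s_flex[["sd_percent"]]))
  invisible(list(rates = rates, variation_docking = v_dock,
                 variation_flexible = v_flex, summary_docking = s_dock,
                 summary_flexible = s_flex))
}
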