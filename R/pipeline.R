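# End-to-end pipeline driver: ingest -> screens -> priorities -> subgroup
# -> onset, with CSV outputs and a reproducibility manifest.

#' Run the full signal-detection pipeline on a corpus directory
#'
#' Reads FAERS-dialect tables and the PT-to-SOC map from `input_dir`,
#' assembles the analysis dataset, runs the PT- and SOC-level
#' disproportionality screens, optionally scores clinical priorities
#' (when an annotations CSV is supplied) and compares two subgroups, and
#' summarizes time to onset. All result tables are written as CSV to
#' `out_dir`, together with a plain-text manifest (configuration echo, row
#' counts, output hashes) sufficient to verify a bit-identical rerun. The
#' screen header notes that no multiple-testing adjustment is applied.
#'
#' @param input_dir directory of `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`, `OUTC.txt` and `pt_soc_map.csv` (as written by
#'   [write_corpus()] or assembled from quarterly files).
#' @param out_dir output directory (created if absent).
#' @param target_names,mode passed to [select_target_reports()].
#' @param criteria a [signal_criteria()].
#' @param rubric a [priority_rubric()].
#' @param annotations_path optional CSV (`term`, `deaths`, `designation`,
#'   `evidence`) enabling priority scoring.
#' @param subgroup optional list(`term_set`, `group_a`, `group_b`,
#'   `group_field`, `method`) enabling a subgroup comparison.
#' @param onset_bins bin edges for [summarize_onset()].
#' @return (invisibly) list with the dataset, screens, priorities, subgroup
#'   row, onset summary, and the manifest path.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         target_names = c("AVACOPAN", "TAVNEOS"),
                         mode = "primary_suspect",
                         criteria = signal_criteria(),
                         rubric = priority_rubric(),
                         annotations_path = NULL,
                         subgroup = NULL,
                         onset_bins = c(0, 30, 60, 90, 180, 360)) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tables <- read_corpus_dir(input_dir)
  dataset <- build_dataset(tables$demo, tables$drug, tables$reac,
                           tables$term_map, outcomes = tables$outc,
                           therapy = tables$ther,
                           target_names = target_names, mode = mode)

  demo_tab <- summarize_demographics(dataset)
  screen_pt <- run_screen(dataset, "pt", criteria)
  screen_soc <- run_screen(dataset, "soc", criteria)

  priorities <- NULL
  if (!is.null(annotations_path)) {
    ann <- readr::read_csv(annotations_path, show_col_types = FALSE,
                           progress = FALSE)
    priorities <- screen_priorities(screen_pt, ann, rubric)
  }

  subgroup_tab <- NULL
  if (!is.null(subgroup)) {
    subgroup_tab <- compare_subgroups(
      dataset, term_set = subgroup$term_set,
      group_field = subgroup$group_field %||% "country",
      group_a = subgroup$group_a, group_b = subgroup$group_b,
      method = subgroup$method %||% "auto")
  }

  obs <- onset_observations(dataset)
  onset <- if (nrow(obs) > 0) summarize_onset(obs$days, onset_bins) else NULL

  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name))
    name
  }
  files <- c(
    wr(demo_tab, "demographics.csv"),
    wr(format_screen(screen_pt), "screen_pt.csv"),
    wr(format_screen(screen_soc), "screen_soc.csv"))
  if (!is.null(priorities)) {
    files <- c(files, wr(format_screen(priorities), "priority.csv"))
  }
  if (!is.null(subgroup_tab)) {
    files <- c(files, wr(subgroup_tab, "subgroup.csv"))
  }
  if (!is.null(onset)) {
    files <- c(files,
               wr(glance(onset), "onset_summary.csv"),
               wr(tidy(onset), "onset_bins.csv"))
  }

  manifest <- write_manifest(
    file.path(out_dir, "manifest.txt"),
    input_dir = input_dir, out_dir = out_dir, files = files,
    settings = list(
      target_names = paste(target_names, collapse = ","),
      mode = mode,
      min_cases = criteria$min_cases,
      ror_lower_gt = criteria$ror_lower_gt,
      ic025_gt = criteria$ic025_gt,
      onset_bins = paste(onset_bins, collapse = ","),
      note = "No multiple-testing adjustment is applied to the screens."),
    counts = list(
      n_reports = dataset$n_total,
      n_target = dataset$n_target,
      n_report_pt_pairs = nrow(dataset$report_pt),
      n_report_soc_pairs = nrow(dataset$report_soc),
      n_pt_screened = nrow(screen_pt),
      n_soc_screened = nrow(screen_soc),
      n_pt_signals = sum(screen_pt$signal),
      n_soc_signals = sum(screen_soc$signal),
      n_onset_observations = nrow(obs)))

  invisible(list(dataset = dataset, demographics = demo_tab,
                 screen_pt = screen_pt, screen_soc = screen_soc,
                 priorities = priorities, subgroup = subgroup_tab,
                 onset = onset, manifest = manifest))
}

# Deterministic plain-text manifest: settings, row counts, md5 of outputs.
# Deliberately no timestamp, so identical inputs yield identical manifests.
write_manifest <- function(path, input_dir, out_dir, files, settings,
                           counts) {
  hashes <- tools::md5sum(file.path(out_dir, files))
  lines <- c(
    "faersignal run manifest",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("faersignal"))),
    sprintf("input_dir: %s", input_dir),
    "",
    "[settings]",
    sprintf("%s: %s", names(settings), unlist(settings)),
    "",
    "[counts]",
    sprintf("%s: %s", names(counts), unlist(counts)),
    "",
    "[outputs]",
    sprintf("%s md5=%s", files, unname(hashes)))
  writeLines(lines, path)
  path
}
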