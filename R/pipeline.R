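# End-to-end design workflow: staged fine-tuning of a pre-trained CLM,
# beam sampling at every checkpoint of an epoch window, validity filtering,
# canonical deduplication, novelty flagging and global ranking by beam
# score. Scores from different epochs are pooled and compared directly;
# duplicate molecules keep the maximum score over their occurrences.

#' Define a staged fine-tuning schedule
#'
#' A schedule is an ordered list of fine-tuning stages, each a corpus plus
#' an epoch count, and a sampling window of final-stage epochs at which the
#' model is decoded. The canonical two-stage protocol fine-tunes first on a
#' few hundred target ligands, then on a handful of template molecules, and
#' samples epochs 5 through 16 of the last stage — early epochs are skipped
#' so the model has absorbed the features of the small fine-tuning set
#' before decoding starts.
#'
#' @param stages A list of stages, each a list with `corpus` (character
#'   vector of SMILES, or a file path) and `epochs` (>= 1); optionally
#'   `label`.
#' @param window Integer pair `c(first, last)` of final-stage epochs to
#'   sample (1-based, inclusive).
#' @return An object of class `beamchem_schedule`.
#' @export
finetune_schedule <- function(stages, window) {
  stopifnot(is.list(stages), length(stages) >= 1,
            length(window) == 2, window[1] >= 1, window[2] >= window[1])
  stages <- lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    stopifnot(!is.null(st$corpus), !is.null(st$epochs), st$epochs >= 1)
    if (is.character(st$corpus) && length(st$corpus) == 1 &&
        file.exists(st$corpus))
      st$corpus <- read_smiles_file(st$corpus)
    if (is.null(st$label)) st$label <- paste0("stage", i)
    st
  })
  last_epochs <- stages[[length(stages)]]$epochs
  if (window[2] > last_epochs)
    stop(sprintf("sampling window end (%d) exceeds final-stage epochs (%d)",
                 window[2], last_epochs))
  structure(list(stages = stages, window = as.integer(window)),
            class = "beamchem_schedule")
}

#' Beam-sampling configuration for the pipeline
#'
#' @param width_k Beam width (default 64).
#' @param max_length Maximum emission steps (default: the model's).
#' @param length_normalize,keep_truncated See [beam_search()].
#' @return A list of class `beamchem_beamconfig`.
#' @export
beam_config <- function(width_k = 64, max_length = NULL,
                        length_normalize = FALSE, keep_truncated = FALSE) {
  structure(list(width_k = as.integer(width_k), max_length = max_length,
                 length_normalize = length_normalize,
                 keep_truncated = keep_truncated),
            class = "beamchem_beamconfig")
}

#' Run a staged fine-tuning and beam-sampling campaign
#'
#' Executes the fine-tuning stages sequentially, each initialized from the
#' previous stage's final checkpoint; decodes every final-stage checkpoint
#' in the sampling window with beam search; and pools all generated strings
#' through [filter_and_rank()]. The window is validated before any training
#' starts.
#'
#' @param pretrained A `beamchem_clm` checkpoint to start from.
#' @param schedule A [finetune_schedule()].
#' @param beam A [beam_config()].
#' @param pretrain_corpus Optional pre-training corpus, included in the
#'   novelty reference when given.
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @param verbose Print stage progress.
#' @return A `beamchem_library` (see [filter_and_rank()]) whose
#'   `provenance` records the schedule, beam settings and epoch losses.
#' @export
run_schedule <- function(pretrained, schedule, beam = beam_config(),
                         pretrain_corpus = NULL, checkpoint_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(pretrained, "beamchem_clm"),
            inherits(schedule, "beamchem_schedule"))
  n_stages <- length(schedule$stages)
  window <- schedule$window
  if (window[2] > schedule$stages[[n_stages]]$epochs)
    stop("sampling window exceeds trained epochs")
  ckpt <- pretrained
  logs <- list()
  fit <- NULL
  for (i in seq_len(n_stages)) {
    st <- schedule$stages[[i]]
    keep <- if (i == n_stages) window[1]:window[2] else st$epochs
    fit <- train_clm(st$corpus, epochs = st$epochs, init = ckpt,
                     stage_label = st$label, keep_epochs = keep,
                     checkpoint_dir = checkpoint_dir, verbose = verbose)
    logs[[st$label]] <- fit$log
    ckpt <- fit$final
  }
  raw <- NULL
  for (ep in window[1]:window[2]) {
    ck <- fit$checkpoints[[paste0("epoch_", ep)]]
    des <- beam_search(ck, width_k = beam$width_k,
                       max_length = beam$max_length,
                       length_normalize = beam$length_normalize,
                       keep_truncated = beam$keep_truncated,
                       verify = FALSE)
    if (nrow(des))
      raw <- rbind(raw, data.frame(string = des$string,
                                   log_score = des$log_score,
                                   epoch = ep, stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("epoch %d: %d completed strings", ep,
                      if (is.null(des)) 0L else nrow(des)))
  }
  if (is.null(raw))
    raw <- data.frame(string = character(0), log_score = numeric(0),
                      epoch = integer(0))
  corpora <- c(list(pretrain_corpus),
               lapply(schedule$stages, `[[`, "corpus"))
  corpora <- Filter(Negate(is.null), corpora)
  lib <- filter_and_rank(raw, training_corpora = corpora)
  lib$provenance <- list(schedule = schedule, beam = beam, logs = logs)
  lib
}

#' Filter, deduplicate and rank generated strings
#'
#' The pooled post-processing of the design workflow: (1) strings that fail
#' chemical-validity parsing are dropped and counted; (2) survivors are
#' canonicalized; (3) duplicate molecules are merged, keeping the maximum
#' log-score and its source epoch; (4) molecules whose canonical form occurs
#' in any training corpus are flagged `is_novel = FALSE` but retained, so
#' the memorization rate stays reportable; (5) ranks are assigned by
#' descending best log-score, ties broken lexicographically by canonical
#' SMILES.
#'
#' @param raw A data.frame with columns `string`, `log_score`, `epoch` (or
#'   a list of such rows).
#' @param training_corpora List of character vectors of training SMILES.
#' @return An object of class `beamchem_library`: `records` (data.frame
#'   `rank`, `canonical_smiles`, `log_score`, `probability`,
#'   `source_epoch`, `is_novel`) and `report` (validity counts and
#'   dialect).
#' @export
filter_and_rank <- function(raw, training_corpora = list()) {
  stopifnot(is.data.frame(raw),
            all(c("string", "log_score", "epoch") %in% names(raw)))
  n_raw <- nrow(raw)
  can <- canonical_smiles(raw$string)
  valid <- !is.na(can)
  n_invalid <- sum(!valid)
  df <- data.frame(canonical_smiles = can[valid],
                   log_score = raw$log_score[valid],
                   source_epoch = raw$epoch[valid],
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    ord <- order(df$canonical_smiles, -df$log_score, df$source_epoch,
                 method = "radix")
    df <- df[ord, , drop = FALSE]
    first <- !duplicated(df$canonical_smiles)
    n_dup <- nrow(df) - sum(first)
    df <- df[first, , drop = FALSE]
  } else n_dup <- 0L
  ref <- unique(stats::na.omit(unlist(
    lapply(training_corpora, canonical_smiles))))
  df$is_novel <- !(df$canonical_smiles %in% ref)
  ord <- order(-df$log_score, df$canonical_smiles, method = "radix")
  df <- df[ord, , drop = FALSE]
  records <- data.frame(rank = seq_len(nrow(df)),
                        canonical_smiles = df$canonical_smiles,
                        log_score = df$log_score,
                        probability = exp(df$log_score),
                        source_epoch = df$source_epoch,
                        is_novel = df$is_novel,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records,
                 report = list(n_raw = n_raw,
                               n_invalid = n_invalid,
                               n_valid = n_raw - n_invalid,
                               n_unique = nrow(records),
                               n_duplicate_merged = n_dup,
                               validity_dialect = paste(
                                 "well-formedness pre-check (balanced",
                                 "parentheses, matched ring closures) +",
                                 "Open Babel default valence parse"))),
            class = "beamchem_library")
}

#' @export
print.beamchem_library <- function(x, ...) {
  r <- x$report
  cat(sprintf("Design library: %d unique molecules (%d raw, %d invalid, %d duplicates merged)\n",
              r$n_unique, r$n_raw, r$n_invalid, r$n_duplicate_merged))
  if (nrow(x$records))
    print(utils::head(x$records, 5))
  invisible(x)
}

#' Write a design library to disk
#'
#' Writes the ranked designs as CSV and the run manifest (validity report
#' plus provenance summary) as JSON.
#'
#' @param library A `beamchem_library`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_design_library <- function(library, dir) {
  stopifnot(inherits(library, "beamchem_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "designs.csv")
  utils::write.csv(library$records, csv, row.names = FALSE)
  manifest <- list(report = library$report,
                   n_records = nrow(library$records))
  if (!is.null(library$provenance)) {
    pv <- library$provenance
    manifest$beam <- pv$beam[c("width_k", "length_normalize")]
    manifest$window <- pv$schedule$window
    manifest$stage_epochs <- vapply(pv$schedule$stages, `[[`, numeric(1), "epochs")
  }
  js <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
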