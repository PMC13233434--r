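# Pipeline orchestration: load a family (structures + optional DSSP files
# + group map), run anchoring and the three analysis layers, and write a
# report bundle (TSV/JSON) plus a manifest capturing every materialized
# parameter so a run can be reproduced exactly. A thin command-line
# wrapper over these functions ships in inst/scripts/robfold.

.defaultConfig <- function() {
  list(structures_dir = NULL, dssp_dir = NULL, group_map = NULL,
       motif_name = "CXXC", motif_regex = "C..C",
       chain = NULL, radius_step = 10L, max_radius = 200L,
       include_motif_window = TRUE, overlapping = TRUE,
       consensus_threshold = 1, ss_thresholds = c(0.5, 1),
       min_run = 2L, rmsd_cutoff = 15, null_n = 50L, seed = 1L,
       benchmark_reference = NULL, out_dir = "robfold_out")
}

#' Load and merge a run configuration
#'
#' Fills a configuration list with package defaults; unknown keys are an
#' error. A YAML file can be supplied through the CLI wrapper.
#'
#' @param config named list of overrides.
#' @return Complete configuration list.
#' @export
runConfig <- function(config = list()) {
  base <- .defaultConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  if (!is.null(base$structures_dir) && !dir.exists(base$structures_dir))
    stop("structures_dir does not exist: ", base$structures_dir)
  if (!is.null(base$dssp_dir) && !dir.exists(base$dssp_dir))
    stop("dssp_dir does not exist: ", base$dssp_dir)
  stopifnot(base$radius_step >= 1L, base$max_radius >= base$radius_step,
            base$rmsd_cutoff > 0)
  base
}

.loadFamily <- function(config) {
  paths <- list.files(config$structures_dir,
                      pattern = "\\.(pdb|cif)$", full.names = TRUE)
  if (!length(paths)) stop("no structure files in ", config$structures_dir)
  records <- lapply(sort(paths), parseStructure, chain = config$chain)
  ids <- vapply(records, recordId, character(1))
  if (!is.null(config$dssp_dir)) {
    for (i in seq_along(records)) {
      d <- file.path(config$dssp_dir, paste0(ids[i], ".dssp"))
      if (file.exists(d)) records[[i]] <- parseDssp(d, records[[i]])
    }
  }
  if (!is.null(config$group_map)) {
    gm <- utils::read.delim(config$group_map, stringsAsFactors = FALSE)
    g <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
    for (i in seq_along(records)) {
      if (is.na(g[ids[i]]))
        stop("protein '", ids[i], "' missing from group map")
      proteinGroup(records[[i]]) <- g[ids[i]]
    }
  }
  records
}

.radiiFromConfig <- function(config) {
  r <- seq(config$radius_step, config$max_radius, by = config$radius_step)
  if (isTRUE(config$include_motif_window)) r <- c(0L, r)
  as.integer(r)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full conservation pipeline
#'
#' Executes anchoring, the primary-sequence layer, the secondary-structure
#' layer (when assignments are available) and the geometric layer (on
#' coordinate-complete windows), writing all reports and a JSON manifest
#' to the configured output directory.
#'
#' @param config list accepted by \code{\link{runConfig}}, or an already
#'   loaded family via the \code{records} argument.
#' @param records optional list of \code{\linkS4class{ProteinRecord}}; when
#'   given, \code{structures_dir}/\code{dssp_dir} are ignored.
#' @return Invisibly, a list with the in-memory results (anchors, sets,
#'   curve, consensus, ssConsensus, topology, rmsd, radius, files).
#' @export
runPipeline <- function(config = list(), records = NULL) {
  config <- runConfig(config)
  if (is.null(records)) records <- .loadFamily(config)
  records <- .asRecordList(records)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pattern <- motifPattern(config$motif_name, config$motif_regex)
  radii <- .radiiFromConfig(config)

  anchors <- findAnchorsAll(records, pattern,
                            overlapping = config$overlapping)
  if (nrow(anchors) == 0L) stop("anchoring: no motif occurrences found")
  sets <- buildExpansionSets(records, pattern, radii = radii,
                             overlapping = config$overlapping)
  groupMap <- stats::setNames(
    vapply(records, proteinGroup, character(1)),
    vapply(records, recordId, character(1)))

  files <- c(anchors = .writeTsv(anchors,
               file.path(config$out_dir, "anchors.tsv")),
             windows = .writeTsv(windowTable(sets),
               file.path(config$out_dir, "windows.tsv")))

  # Fold One
  curve <- conservationCurve(sets)
  files["conservation_curve"] <-
    .writeTsv(curve, file.path(config$out_dir, "conservation_curve.tsv"))
  fm <- frequencyMatrix(sets[[as.character(
    sort(as.integer(names(sets)))[min(2L, length(sets))])]])
  cons <- consensusSequence(fm, config$consensus_threshold)
  consLines <- c(sprintf(">consensus threshold=%g window_length=%d",
                         config$consensus_threshold, fm$window_length),
                 as.character(cons),
                 sprintf(">chou_fasman_classes"),
                 chouFasmanClasses(as.character(cons)))
  consPath <- file.path(config$out_dir, "consensus.txt")
  writeLines(consLines, consPath)
  files["consensus"] <- consPath
  fmOut <- data.frame(symbol = rownames(fm$counts), fm$counts,
                      check.names = FALSE)
  names(fmOut) <- c("symbol", paste0("pos", seq_len(fm$window_length)))
  files["frequency_matrix"] <-
    .writeTsv(fmOut, file.path(config$out_dir, "frequency_matrix.tsv"))

  # Fold Two
  ssCons <- NULL; topo <- NULL
  hasSS <- all(!vapply(records, function(r) is.na(ss3(r)), logical(1)))
  if (hasSS) {
    aln <- alignSecondary(sets[[as.character(
      sort(as.integer(names(sets)))[min(2L, length(sets))])]])
    ssCons <- lapply(config$ss_thresholds, function(th)
      ssConsensus(aln, th))
    names(ssCons) <- paste0("t", config$ss_thresholds)
    ssPath <- file.path(config$out_dir, "ss_consensus.txt")
    writeLines(unlist(lapply(ssCons, function(sc)
      c(sprintf(">ss_consensus threshold=%g", sc$threshold), sc$labels,
        paste(round(100 * ifelse(is.na(sc$support), 0, sc$support)),
              collapse = " ")))), ssPath)
    files["ss_consensus"] <- ssPath
  }

  # Fold Three
  rmsd <- NULL; radius <- NULL
  hasCoords <- any(vapply(sets[[1L]], function(w) w@coordComplete,
                          logical(1)))
  if (hasCoords) {
    structSets <- filterRepresentative(sets, groupMap, structural = TRUE)
    rmsd <- pairwiseRMSD(structSets, cutoff = config$rmsd_cutoff)
    files["rmsd_pairs"] <- .writeTsv(rmsd$records,
      file.path(config$out_dir, "rmsd_pairs.tsv"))
    files["rmsd_summary"] <- .writeTsv(rmsd$summary,
      file.path(config$out_dir, "rmsd_summary.tsv"))
    radius <- conservationRadius(rmsd$summary, config$rmsd_cutoff)
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("robfold")),
                   config = config[order(names(config))],
                   n_records = length(records),
                   n_anchor_sites = nrow(anchors),
                   window_lengths = sort(as.integer(names(sets))),
                   conservation_radius =
                     if (is.null(radius)) NULL else radius)
  mPath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files["manifest"] <- mPath
  invisible(list(anchors = anchors, sets = sets, curve = curve,
                 consensus = cons, ssConsensus = ssCons, rmsd = rmsd,
                 radius = radius, files = files))
}

#' Run the null-model experiment and write its reports
#'
#' @inheritParams runPipeline
#' @return Invisibly, the \code{\link{nullDecayExperiment}} result plus
#'   output paths.
#' @export
runNull <- function(config = list(), records = NULL) {
  config <- runConfig(config)
  if (is.null(records)) records <- .loadFamily(config)
  records <- .asRecordList(records)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pattern <- motifPattern(config$motif_name, config$motif_regex)
  sites <- findAnchorsAll(records, pattern,
                          overlapping = config$overlapping)
  if (nrow(sites) == 0L) stop("no biological anchors found")
  radii <- setdiff(.radiiFromConfig(config), 0L)
  exp <- nullDecayExperiment(records, sites, n = config$null_n,
                             seed = config$seed, radii = radii)
  files <- c(
    null_curves = .writeTsv(exp$null_curves,
      file.path(config$out_dir, "null_curves.tsv")),
    biological_curve = .writeTsv(exp$biological,
      file.path(config$out_dir, "biological_curve.tsv")),
    envelope = .writeTsv(exp$envelope,
      file.path(config$out_dir, "null_envelope.tsv")))
  jsonlite::write_json(
    list(n_trials = config$null_n, seed = config$seed,
         si_metric = "mean pairwise sequence identity (percent)"),
    file.path(config$out_dir, "null_summary.json"), auto_unbox = TRUE)
  invisible(c(exp, list(files = files)))
}

#' Benchmark predicted against reference site tables
#'
#' Reads two TSV site tables (protein_id, motif, start, end; the motif
#' column groups sites into per-motif results) and writes per-motif and
#' micro-averaged IoU benchmark metrics.
#'
#' @param predPath,refPath TSV paths.
#' @param iouMin IoU matching threshold.
#' @param outDir output directory.
#' @return Invisibly, list(per_motif, micro).
#' @export
runBenchmark <- function(predPath, refPath, iouMin = 0.5,
                         outDir = "robfold_out") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pred <- utils::read.delim(predPath, stringsAsFactors = FALSE)
  ref <- utils::read.delim(refPath, stringsAsFactors = FALSE)
  if (!"motif" %in% names(pred)) pred$motif <- "motif"
  if (!"motif" %in% names(ref)) ref$motif <- "motif"
  motifs <- sort(unique(c(pred$motif, ref$motif)))
  per <- lapply(motifs, function(mo)
    matchSitesIoU(pred[pred$motif == mo, , drop = FALSE],
                  ref[ref$motif == mo, , drop = FALSE], iouMin = iouMin))
  names(per) <- motifs
  micro <- microAverage(per)
  tab <- do.call(rbind, lapply(motifs, function(mo) {
    x <- per[[mo]]
    data.frame(motif = mo, n_pred = x$n_pred, n_ref = x$n_ref, TP = x$TP,
               FP = x$FP, FN = x$FN, precision = x$precision,
               recall = x$recall, f1 = x$f1, mean_iou = x$mean_iou)
  }))
  tab <- rbind(tab, data.frame(motif = "micro_avg", n_pred = sum(tab$n_pred),
               n_ref = sum(tab$n_ref), TP = micro$TP, FP = micro$FP,
               FN = micro$FN, precision = micro$precision,
               recall = micro$recall, f1 = micro$f1, mean_iou = NA))
  .writeTsv(tab, file.path(outDir, "benchmark.tsv"))
  invisible(list(per_motif = per, micro = micro, table = tab))
}
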