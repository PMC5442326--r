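#' @title End-to-end analysis pipeline
#' @description
#' Orchestrates per-model hydrogen-bond detection, pair/quartet
#' classification, crisscross detection and geometry tables into one
#' deterministic report, including an overall topology call: an
#' AGCGA-quadruplex of type 1 has stacked GAGA-quartets plus at least one
#' GCGC-quartet in its core, type 2 has central G-C pairs with peripheral
#' G-A pairs but no GAGA-quartet stack.
#' @name pipeline
NULL

#' Default analysis configuration
#'
#' @return named list of tunables: hydrogen-bond cutoffs (`d_max`,
#'   `theta_min`), crisscross `twist_min`, consensus fraction, scanner
#'   spacer ranges, NOE classification cutoffs, groove thresholds
#' @export
default_config <- function() {
  list(d_max = 3.5, theta_min = 120, twist_min = 35, consensus_frac = 0.5,
       min_spacer = 1, max_spacer = 20, g4_min_spacer = 1, g4_max_spacer = 7,
       noe_cutoffs = c(3.0, 4.2, 5.5), groove_thresholds = c(4, 9),
       stack_max_dist = 6.5)
}

#' Canonical configuration signature
#'
#' Deterministic key=value serialization recorded in every report so that
#' outputs are traceable to their configuration.
#' @param config configuration list
#' @return single string
#' @export
config_signature <- function(config = default_config()) {
  config <- config[order(names(config))]
  paste(vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 10), collapse = ",")),
    character(1)), collapse = ";")
}

# quartet stack order along the mean helix axis (first principal direction
# of quartet centers)
.quartet_stack_order <- function(model, quartets) {
  if (nrow(quartets) < 2) return(quartets)
  centers <- t(vapply(quartets$residues, function(rs) {
    keys <- strsplit(rs, ",", fixed = TRUE)[[1]]
    xyz <- lapply(keys, function(k) {
      p <- strsplit(k, ":", fixed = TRUE)[[1]]
      sub <- model[model$chain == p[1] & model$resno == as.numeric(p[2]), ]
      colMeans(as.matrix(sub[, c("x", "y", "z")]))
    })
    Reduce(`+`, xyz) / length(xyz)
  }, numeric(3)))
  axis <- svd(scale(centers, scale = FALSE))$v[, 1]
  proj <- centers %*% axis
  ord <- order(proj)
  out <- quartets[ord, , drop = FALSE]
  out$stack_position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.call_topology <- function(quartets, pairs, model, stack_max_dist = 6.5) {
  n_gaga <- sum(quartets$quartet_class == "GAGA")
  n_gcgc <- sum(quartets$quartet_class %in% c("GCGC_MINOR", "GCGC_MAJOR"))
  n_gc_pairs <- sum(pairs$class == "WC_GC")
  n_ga_pairs <- sum(pairs$class == "GA_N1N7_CARBONYLAMINO")
  if (n_gaga >= 2 && n_gcgc >= 1) return("TYPE1")
  if (n_gaga == 0 && n_gc_pairs >= 4 && n_ga_pairs >= 1) return("TYPE2")
  "none"
}

#' Analyze a structure ensemble
#'
#' Runs hydrogen-bond detection, pair and quartet classification,
#' crisscross detection, torsion/pucker profiling and groove analysis on
#' every model; aggregates consensus pairs/quartets (present in at least
#' `consensus_frac` of models), a per-residue glycosidic-class report
#' (majority vote across models) and the overall topology call.
#'
#' @param x StructureEnsemble or path to a PDB/mmCIF file
#' @param config configuration list from [default_config()]
#' @return object of class AnalysisReport
#' @export
analyze_structure <- function(x, config = default_config()) {
  ens <- if (inherits(x, "StructureEnsemble")) x else read_structure(x)
  nm <- n_models(ens)
  per_model <- vector("list", nm)
  for (m in seq_len(nm)) {
    model <- get_model(ens, m)
    hb <- find_hbonds(model, d_max = config$d_max,
                      theta_min = config$theta_min)
    pairs <- find_pairs(model, hbonds = hb)
    quartets <- assemble_quartets(model, pairs, hb)
    quartets <- .quartet_stack_order(model, quartets)
    criss <- detect_crisscross(model, pairs, twist_min = config$twist_min,
                               max_center_dist = config$stack_max_dist)
    tors <- torsion_table(model)
    grooves <- groove_widths(model, thresholds = config$groove_thresholds)
    per_model[[m]] <- list(model = m, hbonds = hb, pairs = pairs,
                           quartets = quartets, crisscross = criss,
                           torsions = tors, grooves = grooves)
  }
  pairs_cons <- consensus_table(lapply(per_model, `[[`, "pairs"),
                                c("chain_i", "res_i", "chain_j", "res_j",
                                  "class"), config$consensus_frac)
  quart_cons <- consensus_table(lapply(per_model, `[[`, "quartets"),
                                c("quartet_class", "residues"),
                                config$consensus_frac)
  chi_report <- NULL
  tors1 <- per_model[[1]]$torsions
  if (!is.null(tors1) && nrow(tors1)) {
    key <- paste(tors1$chain, tors1$resno)
    cls <- vapply(seq_along(key), function(i) {
      votes <- vapply(per_model, function(pm) pm$torsions$chi_class[i],
                      character(1))
      names(sort(table(votes), decreasing = TRUE))[1]
    }, character(1))
    chi_report <- data.frame(chain = tors1$chain, resno = tors1$resno,
                             restype = tors1$restype, chi_class = cls,
                             stringsAsFactors = FALSE)
  }
  topology <- .call_topology(per_model[[1]]$quartets, per_model[[1]]$pairs,
                             get_model(ens, 1), config$stack_max_dist)
  structure(list(
    provenance = list(source = ens$source, format = ens$format,
                      n_models = nm, config = config_signature(config)),
    per_model = per_model,
    consensus = list(pairs = pairs_cons, quartets = quart_cons),
    chi_report = chi_report,
    topology = topology,
    warnings = character(0)), class = "AnalysisReport")
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport:", x$provenance$source, "\n")
  cat(sprintf("  %d model(s); topology call: %s\n",
              x$provenance$n_models, x$topology))
  cat(sprintf("  consensus: %d pair(s), %d quartet(s)\n",
              nrow(x$consensus$pairs), nrow(x$consensus$quartets)))
  if (nrow(x$consensus$quartets)) {
    cat("  quartet classes:",
        paste(x$consensus$quartets$quartet_class, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize an AnalysisReport to JSON
#'
#' @param report AnalysisReport
#' @param path output file
#' @export
write_report <- function(report, path) {
  payload <- list(
    provenance = report$provenance,
    topology = report$topology,
    consensus_pairs = report$consensus$pairs,
    consensus_quartets = report$consensus$quartets,
    chi_report = report$chi_report,
    crisscross = report$per_model[[1]]$crisscross)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Scan a FASTA file for both consensus motifs
#'
#' @param path FASTA file
#' @param config configuration list
#' @param out_prefix optional path prefix; writes `<prefix>.bed`,
#'   `<prefix>.tsv` and `<prefix>_summary.tsv`
#' @return list(matches, summary)
#' @export
scan_fasta <- function(path, config = default_config(), out_prefix = NULL) {
  seqs <- read_fasta_dna(path)
  ag <- scan_agcga(seqs, min_spacer = config$min_spacer,
                   max_spacer = config$max_spacer)
  g4 <- scan_g4(seqs, min_spacer = config$g4_min_spacer,
                max_spacer = config$g4_max_spacer)
  matches <- rbind(ag, g4)
  n_rep <- vapply(seqs, function(s) count_repeats(s)$n, numeric(1))
  summary <- data.frame(
    seq_id = names(seqs),
    length = nchar(seqs),
    n_agcga_repeats = as.integer(n_rep),
    n_agcga_matches = as.integer(table(factor(ag$seq_id,
                                              levels = names(seqs)))),
    n_g4_matches = as.integer(table(factor(g4$seq_id, levels = names(seqs)))),
    stringsAsFactors = FALSE)
  summary$dual_consensus <- summary$n_agcga_matches >= 1 &
    summary$n_g4_matches >= 1
  if (!is.null(out_prefix)) {
    write_motif_bed(matches, paste0(out_prefix, ".bed"))
    write_motif_tsv(matches, paste0(out_prefix, ".tsv"))
    utils::write.table(summary, paste0(out_prefix, "_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(matches = matches, summary = summary)
}
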