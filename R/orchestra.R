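# End-to-end pipeline: synthetic trio -> monomer-rate comparison ->
# methylation segmentation/phylogeny/SVM -> Hi-C anchoring -> SV calling and
# polarization -> TSS regulatory statistics, with a single structured
# report.

#' Extract the carrier-coordinate insertion table from polarized events
#'
#' @param events Output of [polarize_genome_events()].
#' @param strain_q,strain_t The strain names used in that call.
#' @return data.frame: strain, chromosome, start, end of each insertion's
#'   inserted segment.
#' @export
insertions_table <- function(events, strain_q = "strainA",
                             strain_t = "strainB") {
  ins <- events[events$type == "insertion" & !is.na(events$strain), ,
                drop = FALSE]
  if (!nrow(ins))
    return(data.frame(strain = character(), chromosome = character(),
                      start = integer(), end = integer()))
  start <- ifelse(ins$strain == strain_q, ins$q_gap_start, ins$t_gap_start)
  data.frame(strain = ins$strain, chromosome = ins$chromosome,
             start = start, end = start + ins$size - 1)
}

#' Run the full synthetic-trio analysis pipeline
#'
#' Stages run in dependency order; a disabled stage simply leaves its block
#' out of the report. All randomness derives from `config$seed`.
#'
#' @param config A [trio_config()].
#' @param stages Character vector among `"repeats"`, `"methylome"`, `"hic"`,
#'   `"sv"`, `"tss"`.
#' @param monomers_per_chromosome Monomer subsample used by the repeat stage.
#' @param report_path Optional path; the report is written there as JSON.
#' @return List of class `trio_report` with one element per executed stage
#'   plus `provenance`.
#' @export
run_trio_pipeline <- function(config,
                              stages = c("repeats", "methylome", "hic", "sv",
                                         "tss"),
                              monomers_per_chromosome = 40,
                              report_path = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  trio <- generate_trio(config)
  genomes <- trio$genomes; truth <- trio$truth
  report <- list(provenance = list(seed = config$seed,
                                   config = unclass(config),
                                   package_version =
                                     as.character(utils::packageVersion("cenevol"))))

  if ("repeats" %in% stages && !is.null(truth$centromeres)) {
    mono <- truth_monomers(genomes, truth, "strainA",
                           max_per_chromosome = monomers_per_chromosome)
    sets <- lapply(split(mono, mono$chromosome), cluster_monomers,
                   threshold = 0.9, min_members_for_representative = 3L)
    classes <- setNames(truth$centromeres$class, truth$centromeres$chromosome)
    rec <- best_match_associations(sets, classes)
    cmp <- try(compare_similarity_groups(rec), silent = TRUE)
    report$repeats <- list(records = rec,
                           comparison = if (inherits(cmp, "try-error"))
                             NULL else cmp)
  }

  if ("methylome" %in% stages && !is.null(truth$centromeres)) {
    regions <- list()
    for (st in truth$phylogeny$ingroup) {
      meth <- generate_methylation(genomes, truth, config, strain = st)
      if (is.null(meth$calls)) next
      for (chrom in unique(meth$calls$chromosome)) {
        segs <- segment_regions(meth$calls[meth$calls$chromosome == chrom, ],
                                min_cpgs = config$min_domain_cpgs)
        if (!nrow(segs)) next
        segs$strain <- st
        segs$sequence <- substring(genomes[[st]][[chrom]], segs$start, segs$end)
        cls <- truth$centromeres$class[truth$centromeres$chromosome == chrom]
        segs$acro <- cls == "acrocentric"
        regions[[length(regions) + 1]] <- segs
      }
    }
    regions <- do.call(rbind, regions)
    report$methylome <- list(regions = regions[, setdiff(names(regions),
                                                         "sequence")])
    if (!is.null(regions) && nrow(regions) >= 2) {
      phylo <- methylation_phylogeny(regions, k = 8)
      report$methylome$newick <- phylo$newick
      hypo <- regions$sequence[regions$status == "hypo"]
      hyper <- regions$sequence[regions$status == "hyper"]
      if (length(hypo) && length(hyper)) {
        svm <- try(svm_discriminate(hypo, hyper, k = 8, mode = "cv5",
                                    seed = config$seed), silent = TRUE)
        if (!inherits(svm, "try-error"))
          report$methylome$svm_accuracy <- svm$accuracy
      }
    }
  }

  if ("hic" %in% stages) {
    hic <- generate_hic_contacts(truth, config)
    model <- fit_nb(hic$contacts, hic$truth_chromosome)
    pred <- vapply(seq_len(nrow(hic$contacts)), function(i)
      classify_orphan(model, hic$contacts[i, ])$chromosome, "")
    report$hic <- list(classification_accuracy =
                         mean(pred == hic$truth_chromosome),
                       n_contigs = nrow(hic$contacts))
  }

  if ("sv" %in% stages) {
    mask <- truth$centromeres
    if (!is.null(mask)) {
      for (i in seq_len(nrow(mask))) {
        mask$start[i] <- anc_to_strain(truth, "strainA", mask$chromosome[i],
                                       mask$start[i])
        mask$end[i] <- anc_to_strain(truth, "strainA", mask$chromosome[i],
                                     mask$end[i])
      }
    }
    events <- polarize_genome_events(genomes$strainA, genomes$strainB,
                                     genomes$outgroup, mask = mask)
    report$sv <- list(events = events,
                      balance = indel_balance_summary(events))
  }

  if ("tss" %in% stages && !is.null(truth$tss)) {
    tssd <- generate_tss_counts(genomes, truth, config)
    if (!is.null(report$sv)) {
      ins <- insertions_table(report$sv$events)
    } else {
      sv <- truth$svs[truth$svs$type == "insertion", , drop = FALSE]
      ins <- data.frame(strain = sv$carrier, chromosome = sv$chromosome,
                        start = sv$carrier_start, end = sv$carrier_end)
    }
    pairs <- find_insertion_tss_pairs(tssd$tss, ins)
    stats_w <- list(); stats_wo <- list()
    if (nrow(pairs)) {
      for (i in seq_len(nrow(pairs))) {
        p <- pairs[i, ]
        cw <- tssd$calls[tssd$calls$strain == p$carrier &
                           tssd$calls$chromosome == p$chromosome, ]
        co <- tssd$calls[tssd$calls$strain == p$partner &
                           tssd$calls$chromosome == p$chromosome, ]
        stats_w[[i]] <- as.data.frame(window_stats(
          genomes[[p$carrier]][[p$chromosome]], p$carrier_pos, p$strand, cw))
        stats_wo[[i]] <- as.data.frame(window_stats(
          genomes[[p$partner]][[p$chromosome]], p$partner_pos, p$strand, co))
      }
      sw <- do.call(rbind, stats_w); so <- do.call(rbind, stats_wo)
      tests <- try(paired_increase_tests(sw, so), silent = TRUE)
      screen <- expression_screen(tssd$counts)
      report$tss <- list(n_pairs = nrow(pairs),
                         tests = if (inherits(tests, "try-error")) NULL else tests,
                         n_significant_expression =
                           sum(screen$p < 0.01, na.rm = TRUE),
                         n_novel = sum(screen$novel, na.rm = TRUE))
    } else {
      report$tss <- list(n_pairs = 0L)
    }
  }

  class(report) <- "trio_report"
  if (!is.null(report_path)) {
    ser <- report
    ser$repeats$records <- NULL
    ser$sv$events <- NULL
    jsonlite::write_json(ser, report_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.trio_report <- function(x, ...) {
  cat("Synthetic trio pipeline report (seed ", x$provenance$seed, ")\n",
      sep = "")
  if (!is.null(x$repeats) && !is.null(x$repeats$comparison)) {
    cat("  monomer similarity medians:\n")
    print(round(x$repeats$comparison$medians, 4))
    cat("  rank-sum p (NonAcroNonAcro lower): ",
        format(x$repeats$comparison$p_values, digits = 3), "\n")
  }
  if (!is.null(x$methylome)) {
    cat("  methylation regions: ", nrow(x$methylome$regions), "\n")
    if (!is.null(x$methylome$svm_accuracy))
      cat("  hypo/hyper SVM 5-fold accuracy: ",
          round(x$methylome$svm_accuracy, 3), "\n")
  }
  if (!is.null(x$hic))
    cat("  Hi-C naive-Bayes self-classification accuracy: ",
        round(x$hic$classification_accuracy, 4), " (", x$hic$n_contigs,
        " contigs)\n", sep = "")
  if (!is.null(x$sv)) {
    cat("  polarized SV events: ", nrow(x$sv$events), "; ins:del ratio ",
        format(x$sv$balance$ratio, digits = 3), "\n", sep = "")
  }
  if (!is.null(x$tss)) {
    cat("  insertion-linked TSS pairs: ", x$tss$n_pairs, "\n")
    if (!is.null(x$tss$tests)) {
      cat("  paired one-sided p (gc/cpg/unmethylated): ",
          paste(format(x$tss$tests$p_values, digits = 3), collapse = " / "),
          "\n")
    }
  }
  invisible(x)
}
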