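#' Run the full tag-SNP selection pipeline
#'
#' Read -> cluster -> optimize -> (optionally) evaluate: clusters the loci
#' by fuzzy LD equivalence at level `lambda`, selects `n_tags` tags from
#' the class centers with the constrained binary PSO, and scores the tag
#' set by leave-one-out SVM imputation of the non-tag genotypes.
#'
#' @param hm A [haplotype_matrix()].
#' @param n_tags Number of tag SNPs to select.
#' @param lambda LD equivalence cut level; see [ld_cluster()].
#' @param swarm A [swarm_config()].
#' @param svm An [impute_config()].
#' @param seed Optional integer seed driving every random draw in the run.
#' @param evaluate If `TRUE` (default), compute [loocv_accuracy()] of the
#'   selected tags; skip with `FALSE` when only the tag set is needed.
#' @return A `tag_run` object: `clustering`, `selection`, `accuracy`
#'   (`NULL` when not evaluated), `n_tags`, `lambda`, `seed`, `elapsed`
#'   (seconds, informational). [glance()] gives a one-row summary.
#' @examples
#' sim <- simulate_haplotypes(n_haplotypes = 60, n_blocks = 3,
#'                            loci_per_block = 4, seed = 2)
#' run <- select_tags(sim$haplotypes, n_tags = 3, seed = 2)
#' glance(run)
#' @export
select_tags <- function(hm, n_tags, lambda = 0.8, swarm = swarm_config(),
                        svm = impute_config(), seed = NULL,
                        evaluate = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  clus <- ld_cluster(hm, lambda = lambda)
  sel <- bpso_select(clus, n_tags = n_tags, config = swarm, seed = seed)
  acc <- if (evaluate) loocv_accuracy(hm, sel$tags, config = svm) else NULL
  out <- list(clustering = clus,
              selection = sel,
              accuracy = acc,
              n_tags = as.integer(n_tags),
              lambda = lambda,
              seed = seed,
              elapsed = proc.time()[["elapsed"]] - t0)
  class(out) <- "tag_run"
  out
}

#' @export
print.tag_run <- function(x, ...) {
  cat(sprintf("<tag_run> lambda = %s: %d loci -> %d candidates -> %d tags (fitness %.4f)\n",
              format(x$lambda), x$clustering$m,
              length(x$clustering$centers), x$n_tags,
              x$selection$fitness))
  if (!is.null(x$accuracy)) {
    cat(sprintf("LOOCV imputation accuracy: %.4f\n", x$accuracy$acc))
  }
  invisible(x)
}

read_hap_input <- function(input) {
  if (grepl("\\.vcf(\\.gz)?$", input, ignore.case = TRUE)) {
    read_hap_vcf(input)
  } else {
    read_hap_matrix(input)
  }
}

run_record <- function(run, input = NULL) {
  sel <- run$selection
  list(input = input,
       seed = run$seed,
       lambda = run$lambda,
       n_tags = run$n_tags,
       swarm = unclass(sel$config),
       svm = if (is.null(run$accuracy)) NULL else unclass(run$accuracy$config),
       n_loci = run$clustering$m,
       n_candidates = length(run$clustering$centers),
       class_sizes = run$clustering$class_size,
       tags = sel$tag_ids,
       fitness = sel$fitness,
       fitness_history = sel$history,
       accuracy = if (is.null(run$accuracy)) NULL else list(
         acc = run$accuracy$acc,
         n_samples = run$accuracy$n_samples,
         n_nontag = run$accuracy$n_nontag,
         total_comparisons = run$accuracy$total_comparisons,
         per_fold_errors = run$accuracy$per_fold_errors))
}

#' Pipeline command: select tags from a haplotype file
#'
#' Reads a plain-text haplotype matrix (or phased VCF, by extension),
#' runs [select_tags()], and writes `tags.tsv` (locus_id, class_size),
#' `clusters.tsv` (locus_id, class_index, is_center, class_size) and
#' `run_record.json` to `out_dir`. The resolved configuration is logged
#' before computing; outputs are byte-identical across runs with the same
#' seed.
#'
#' @param input Path to the haplotype file.
#' @param out_dir Output directory (created if needed).
#' @param n_tags,lambda,swarm,svm,seed,evaluate Passed to [select_tags()].
#' @param quiet Suppress the config log.
#' @return The `tag_run`, invisibly.
#' @export
cmd_select <- function(input, out_dir, n_tags, lambda = 0.8,
                       swarm = swarm_config(), svm = impute_config(),
                       seed = NULL, evaluate = TRUE, quiet = FALSE) {
  hm <- read_hap_input(input)
  if (!quiet) {
    message(sprintf(
      "select: input=%s n=%d m=%d lambda=%s n_tags=%d seed=%s pop=%d iter=%d switch=%s c1=%s c2=%s w=%s v=[%s,%s] gamma=%s cost=%s",
      input, nrow(hm), ncol(hm), format(lambda), n_tags,
      ifelse(is.null(seed), "NULL", seed), swarm$pop_size, swarm$max_iter,
      format(swarm$switch_fraction), format(swarm$c1), format(swarm$c2),
      format(swarm$w), format(swarm$v_min), format(swarm$v_max),
      format(svm$gamma), format(svm$cost)))
  }
  run <- select_tags(hm, n_tags = n_tags, lambda = lambda, swarm = swarm,
                     svm = svm, seed = seed, evaluate = evaluate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clus <- run$clustering
  sel <- run$selection
  utils::write.table(
    data.frame(locus_id = sel$tag_ids,
               class_size = clus$class_size[clus$class_of[sel$tags]]),
    file.path(out_dir, "tags.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    tidy(clus),
    file.path(out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- run_record(run, input = input)
  jsonlite::write_json(rec, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(run)
}

#' Pipeline command: simulate a block-structured haplotype dataset
#'
#' Writes `haplotypes.txt` (plain-text matrix dialect) and `truth.tsv`
#' (locus_id, block) to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [simulate_haplotypes()].
#' @return The simulation list, invisibly.
#' @export
cmd_simulate <- function(out_dir, ...) {
  sim <- simulate_haplotypes(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_hap_matrix(sim$haplotypes, file.path(out_dir, "haplotypes.txt"))
  utils::write.table(sim$truth[, c("locus_id", "block")],
                     file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Pipeline command: evaluate a tag set on a haplotype file
#'
#' Reads the haplotypes and a tags TSV (column `locus_id`; the output of
#' [cmd_select()] works directly), computes [loocv_accuracy()], prints it
#' and writes `evaluation.json` to `out_dir`.
#'
#' @param input Path to the haplotype file.
#' @param tags_file Path to a TSV with a `locus_id` column.
#' @param out_dir Output directory (created if needed).
#' @param svm An [impute_config()].
#' @param quiet Suppress the printed report.
#' @return The `accuracy_report`, invisibly.
#' @export
cmd_evaluate <- function(input, tags_file, out_dir,
                         svm = impute_config(), quiet = FALSE) {
  hm <- read_hap_input(input)
  tags_df <- utils::read.table(tags_file, header = TRUE, sep = "\t",
                               colClasses = "character")
  if (!"locus_id" %in% names(tags_df)) {
    stop("tags file must have a locus_id column", call. = FALSE)
  }
  rep <- loocv_accuracy(hm, tags_df$locus_id, config = svm)
  if (!quiet) print(rep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(input = input, tags = tags_df$locus_id, acc = rep$acc,
         n_samples = rep$n_samples, n_nontag = rep$n_nontag,
         total_comparisons = rep$total_comparisons,
         per_fold_errors = rep$per_fold_errors,
         svm = unclass(svm)),
    file.path(out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}
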