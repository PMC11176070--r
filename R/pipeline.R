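## End-to-end orchestration on synthetic data: one config, seeded stages,
## a manifest of every artifact written.

.pipeline_keys <- c("stages", "seed", "out_dir", "genome",
                    "strand", "celltype", "cis", "cna")

#' Validate and normalize a pipeline run configuration
#'
#' @param config a named list, or path to a YAML file with the same shape.
#'   Recognized keys: stages (subset of strand/celltype/cis/cna), seed,
#'   out_dir, genome (named chrom -> length), and one optional parameter
#'   block per stage. Unknown keys are rejected.
#' @return validated config list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config$stages <- config$stages %||% character(0)
  bad <- setdiff(config$stages, c("strand", "celltype", "cis", "cna"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% tempfile("mosaicscan_run_")
  if (!is.null(config$genome)) config$genome <- unlist(config$genome)
  config
}

.manifest_add <- function(manifest, stage, files, params) {
  manifest$stages[[stage]] <- list(
    params = params,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  manifest
}

#' Run the synthetic-data pipeline end-to-end
#'
#' Executes the requested stages in dependency order, each on synthetic
#' data generated from the stage's parameter block: \code{strand} (simulate
#' strand counts, segment states, call SCEs, fit the hotspot model),
#' \code{celltype} (simulate an NO reference, two-stage feature selection,
#' classifier + LOOCV), \code{cis} (simulate haplotype-tagged CRE counts,
#' sliding-window scan) and \code{cna} (simulate expression, region mixture
#' test, clone assignment). Every stage derives its own seed
#' deterministically from the global seed and the stage name, writes its
#' outputs under \code{out_dir}, and registers them (with md5 hashes) in the
#' returned manifest.
#'
#' @param config list or YAML path accepted by \code{\link{run_config}}.
#' @return the run manifest (invisibly written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- cfg$genome %||% c(chr1 = 5e7, chr2 = 4e7)
  manifest <- list(seed = cfg$seed, out_dir = cfg$out_dir, stages = list())

  if ("strand" %in% cfg$stages) {
    p <- cfg$strand %||% list()
    seed <- derive_seed(cfg$seed, "strand")
    sim <- simulate_strand_cells(sim_config(
      genome, bin_width = p$bin_width %||% 1e6,
      n_cells = p$n_cells %||% 30,
      reads_per_cell = p$reads_per_cell %||% 400 * length(genome),
      sce_rate = p$sce_rate %||% 4,
      background_noise = p$background_noise %||% 0.02, seed = seed))
    seg <- call_strand_states(sim$matrix)
    sces <- detect_sces(seg)
    bins <- make_genome_bins(genome, p$hotspot_bin %||% 5e5)
    counts <- bin_sce_counts(sces$calls, bins)
    files <- c(file.path(cfg$out_dir, "strand_W.tsv.gz"),
               file.path(cfg$out_dir, "strand_C.tsv.gz"),
               file.path(cfg$out_dir, "segments.tsv"),
               file.path(cfg$out_dir, "sce_calls.bed"),
               file.path(cfg$out_dir, "chrom.sizes"))
    write_count_tsv(sim$matrix$W, files[1])
    write_count_tsv(sim$matrix$C, files[2])
    write.table(seg, files[3], sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(sces$calls)) {
      gr <- GenomicRanges::GRanges(
        sces$calls$chrom,
        IRanges::IRanges(as.numeric(sces$calls$ci_start) + 1,
                         as.numeric(sces$calls$ci_end)))
      S4Vectors::mcols(gr)$name <- sces$calls$cell
      S4Vectors::mcols(gr)$flip <- sces$calls$flip
      write_bed(gr, files[4])
    } else file.create(files[4])
    write_chrom_sizes(genome, files[5])
    if (length(unique(counts)) >= 2) {
      ## demo-scale SCE callsets are sparse; the MLE is fine but fitdist's
      ## vcov step can warn about a near-singular hessian
      model <- suppressWarnings(fit_hotspot_model(counts))
      hot <- call_hotspots(bins, counts, model)
      f <- file.path(cfg$out_dir, "hotspots.tsv")
      write.table(hot, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    manifest <- .manifest_add(manifest, "strand", as.list(files),
                              c(p, list(seed = seed)))
  }

  if ("celltype" %in% cfg$stages) {
    p <- cfg$celltype %||% list()
    seed <- derive_seed(cfg$seed, "celltype")
    sim <- simulate_no_matrix(
      n_classes = p$n_classes %||% 4, cells_per_class = p$cells_per_class %||% 25,
      n_genes = p$n_genes %||% 400, signature_size = p$signature_size %||% 20,
      effect = p$effect %||% 1, seed = seed)
    norm <- normalize_no(sim$matrix)
    s1 <- select_features_stage1(norm, n_perm = p$n_perm %||% 10, seed = seed)
    s2 <- select_features_stage2(norm, stage1_genes = s1$gene[s1$selected],
                                 n_perm = p$n_perm %||% 10, seed = seed)
    clf <- train_celltype_classifier(norm, signature_genes = s2$signature$gene)
    post <- classify_cells(clf, sim$matrix)
    files <- c(file.path(cfg$out_dir, "no_counts.tsv.gz"),
               file.path(cfg$out_dir, "signature_genes.tsv"),
               file.path(cfg$out_dir, "celltype_posteriors.tsv"))
    write_count_tsv(sim$matrix$counts, files[1])
    write.table(s2$signature, files[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(post, files[3], sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "celltype", as.list(files),
                              c(p, list(seed = seed)))
  }

  if ("cis" %in% cfg$stages) {
    p <- cfg$cis %||% list()
    seed <- derive_seed(cfg$seed, "cis")
    n_cre <- p$n_cres %||% 200
    cres <- data.frame(chrom = "chrX", start = seq(0, by = 2e4,
                                                   length.out = n_cre))
    cres$end <- cres$start + 1e3
    win <- data.frame(chrom = "chrX", start = 1e6, end = 1.3e6,
                      haplotype = "H1", effect = p$effect %||% 0.5)
    sim <- simulate_cre_haplotype_counts(cres, n_cells = p$n_cells %||% 80,
                                         carrier_fraction = 0.3,
                                         windows = win, seed = seed)
    region <- list(chrom = "chrX", start = 0, end = max(cres$end))
    windows <- make_windows(region, size = p$window %||% 3e5,
                            step = p$step %||% 1e5)
    res <- window_permutation_fdr(sim$counts, sim$counts$genotype, windows,
                                  n_perm = p$n_perm %||% 200, seed = seed)
    f <- file.path(cfg$out_dir, "cis_windows.tsv")
    write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "cis", list(f),
                              c(p, list(seed = seed)))
  }

  if ("cna" %in% cfg$stages) {
    p <- cfg$cna %||% list()
    seed <- derive_seed(cfg$seed, "cna")
    n_genes <- p$n_genes %||% 1000
    genes <- data.frame(gene = sprintf("g%03d", seq_len(n_genes)),
                        chrom = "chr17", start = 1e5 * seq_len(n_genes),
                        end = 1e5 * seq_len(n_genes) + 5e4)
    clones <- data.frame(clone = "del_clone", chrom = "chr17",
                         start = 1e5, end = 1e5 * 25 + 5e4,
                         dosage = p$dosage %||% 0.5,
                         cell_fraction = p$cell_fraction %||% 0.4)
    sim <- simulate_expression(genes, n_cells = p$n_cells %||% 400,
                               clones = clones, seed = seed)
    norm <- normalize_expression(sim$matrix)
    region_genes <- genes$gene[genes$start >= 1e5 & genes$end <= 1e5 * 25 + 5e4]
    fit <- region_mixture_test(norm, region_genes, region_id = "del_clone",
                               seed = seed)
    fit <- adjust_mixture_fdr(list(fit))[[1]]
    out <- list(region = fit$region, n_genes = fit$n_genes_expressed,
                bic1 = fit$bic1, bic2 = fit$bic2, lrt_p = fit$lrt_p,
                q = fit$q, bimodal = fit$bimodal)
    if (isTRUE(fit$bimodal)) {
      cl <- assign_clones(fit, dosage = clones$dosage)
      out$cf <- cl$cf
      f2 <- file.path(cfg$out_dir, "cna_assignments.tsv")
      write.table(data.frame(cell = rownames(sim$matrix$counts),
                             posterior_cna = cl$posterior_cna,
                             assignment = cl$assignment),
                  f2, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    f <- file.path(cfg$out_dir, "cna_region.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA)
    files <- c(f, if (isTRUE(fit$bimodal)) f2)
    manifest <- .manifest_add(manifest, "cna", as.list(files),
                              c(p, list(seed = seed)))
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
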