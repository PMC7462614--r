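#' Assemble a pipeline run configuration
#'
#' Central configuration for [run_pipeline()]. Per-population settings
#' (haploid pool size and coverage bounds) are given as a list of lists;
#' coverage bounds default to half / twice the mean coverage observed in
#' the data when left `NULL`.
#'
#' @param reference,outgroup,gtf,sync input file paths.
#' @param pops list of per-population lists with `name`, `pool_size`, and
#'   optional `min_depth`, `max_depth`.
#' @param out_dir output directory.
#' @param window_size diversity/F_ST window (default 50 kb).
#' @param min_count_diversity minor-allele count for diversity SNPs
#'   (default 2).
#' @param min_count_fst minor-allele count for F_ST SNPs (default 4).
#' @param min_depth_fst minimum coverage for F_ST sites (default 20).
#' @param min_covered_fraction minimum covered window fraction (0.3).
#' @param daf_min,daf_max polymorphic DAF band (0.05, 0.95).
#' @param n_bins DAF bins for alpha(x) (default 9).
#' @param posterior_threshold segregation-filter posterior cutoff (0.9).
#' @param error_rate error rate assumed by the segregation filter.
#' @param outlier_q F_ST outlier tail (default 0.005).
#' @param mu mutation rate per bp per generation for N_e
#'   (default 2.6321e-9).
#' @param sfs_project_n projection size for DFE spectra (default 10).
#' @param dfe_boot bootstrap replicates for the DFE fit (default 200).
#' @param alpha_boot bootstrap replicates for asymptotic alpha (200).
#' @param seed master seed.
#' @param stages stages to run, in dependency order.
#' @return a `run_config` list.
#' @export
run_config <- function(reference, outgroup, gtf, sync, pops, out_dir,
                       window_size = 50000, min_count_diversity = 2,
                       min_count_fst = 4, min_depth_fst = 20,
                       min_covered_fraction = 0.3,
                       daf_min = 0.05, daf_max = 0.95, n_bins = 9,
                       posterior_threshold = 0.9, error_rate = 0.01,
                       outlier_q = 0.005, mu = 2.6321e-9,
                       sfs_project_n = 10, dfe_boot = 200,
                       alpha_boot = 200, seed = 1L,
                       stages = c("sites", "diversity", "fst", "selection")) {
  structure(list(reference = reference, outgroup = outgroup, gtf = gtf,
                 sync = sync, pops = pops, out_dir = out_dir,
                 window_size = window_size,
                 min_count_diversity = min_count_diversity,
                 min_count_fst = min_count_fst,
                 min_depth_fst = min_depth_fst,
                 min_covered_fraction = min_covered_fraction,
                 daf_min = daf_min, daf_max = daf_max, n_bins = n_bins,
                 posterior_threshold = posterior_threshold,
                 error_rate = error_rate, outlier_q = outlier_q, mu = mu,
                 sfs_project_n = sfs_project_n, dfe_boot = dfe_boot,
                 alpha_boot = alpha_boot, seed = as.integer(seed),
                 stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file provides any subset of [run_config()]'s fields;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("reference", "outgroup", "gtf", "sync", "pops", "out_dir")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("config is missing required fields: ", paste(missing, collapse = ", "))
  do.call(run_config, y)
}

.write_table <- function(dt, path, convention) {
  con <- file(path, "w")
  writeLines(paste0("# coordinates: ", convention), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

.read_table <- function(path) data.table::fread(path, skip = 1L)

#' Run the pooled population-genomics pipeline
#'
#' Executes the analysis stages in dependency order on one set of inputs:
#' \describe{
#'   \item{sites}{degeneracy classification of CDS positions and
#'     polarization of every population against the outgroup
#'     pseudogenome, with the posterior segregation filter.}
#'   \item{diversity}{windowed pi and Watterson's theta per population
#'     and N_e from the genome-wide theta.}
#'   \item{fst}{pairwise window/gene/SNP F_ST, the Z_FST outlier scan,
#'     Fisher's exact tests with BH correction, candidate genes, and a
#'     neighbor-joining tree of the genome-wide F_ST matrix (3+
#'     populations).}
#'   \item{selection}{per-gene MK tables, alpha(x) with asymptotic fit,
#'     DoS with percentile gene sets, SFS projection and the gamma DFE
#'     fit.}
#' }
#' All stage outputs are written under `config$out_dir` together with a
#' machine-readable `summary.json` of the headline numbers. Identical
#' configuration and seed give byte-identical summaries.
#'
#' @param config a [run_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  known <- c("sites", "diversity", "fst", "selection")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if ("selection" %in% stages && !"sites" %in% stages)
    stop("stage 'selection' requires stage 'sites'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  pop_names <- vapply(config$pops, `[[`, character(1), "name")
  reference <- read_fasta(config$reference)
  outgroup <- read_fasta(config$outgroup)
  cds <- read_cds_gtf(config$gtf)
  sync <- read_sync(config$sync, pop_names)

  genes <- cds[, .(start = min(start), end = max(end)),
               by = .(gene_id, chrom)]

  # per-population coverage bounds: configured, or [mean/2, 2*mean]
  bounds <- lapply(seq_along(config$pops), function(p) {
    cp <- config$pops[[p]]
    md <- mean(rowSums(sync$counts[[p]]))
    list(min = if (!is.null(cp$min_depth)) cp$min_depth else md / 2,
         max = if (!is.null(cp$max_depth)) cp$max_depth else 2 * md)
  })

  summary <- list(seed = config$seed, populations = pop_names)
  deg <- NULL
  polarized <- NULL

  if ("sites" %in% stages) {
    deg <- classify_degeneracy(reference, cds)
    polarized <- vector("list", length(pop_names))
    names(polarized) <- pop_names
    og_chrom <- outgroup[[sync$chrom[1]]]
    og_base <- substring(og_chrom, sync$pos, sync$pos)
    for (p in seq_along(pop_names)) {
      pol <- polarize(sync$counts[[p]], og_base,
                      min_depth = bounds[[p]]$min,
                      max_depth = bounds[[p]]$max,
                      daf_min = config$daf_min, daf_max = config$daf_max)
      pol[, `:=`(chrom = sync$chrom, pos = sync$pos)]
      # posterior segregation filter on polymorphic calls
      ip <- which(pol$status == "polymorphic")
      if (length(ip)) {
        minor <- pmin(pol$derived_count[ip],
                      pol$total_count[ip] - pol$derived_count[ip])
        keep <- segregation_filter(minor, pol$total_count[ip],
                                   config$posterior_threshold,
                                   config$error_rate)
        demote <- ip[!keep]
        pol$status[demote] <- ifelse(pol$daf[demote] < 0.5,
                                     "monomorphic", "fixed")
      }
      pol <- merge(pol,
                   deg[, .(chrom, pos = pos + 1L, gene_id,
                           degeneracy = class)],
                   by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
      polarized[[p]] <- pol
      .write_table(
        pol[, .(chrom, pos, degeneracy, gene_id, outgroup, derived, daf,
                status)],
        file.path(config$out_dir, sprintf("polarized_%s.tsv", pop_names[p])),
        "1-based closed")
    }
  }

  if ("diversity" %in% stages) {
    div <- list()
    for (p in seq_along(pop_names)) {
      w <- window_stats(sync$counts[[p]], sync$pos, sync$chrom,
                        haploid_pool_size = config$pops[[p]]$pool_size,
                        window_size = config$window_size,
                        min_count = config$min_count_diversity,
                        min_covered_fraction = config$min_covered_fraction,
                        min_depth = bounds[[p]]$min,
                        max_depth = bounds[[p]]$max)
      .write_table(w, file.path(config$out_dir,
                                sprintf("windows_%s.tsv", pop_names[p])),
                   "1-based closed")
      a_n <- watterson_a(config$pops[[p]]$pool_size)
      n_cov <- sum(w$covered_fraction * config$window_size)
      theta <- sum(w$n_snps) / (a_n * n_cov)
      pi <- sum(w$pi * w$covered_fraction * config$window_size) / n_cov
      div[[pop_names[p]]] <- list(
        theta = theta, pi = pi,
        ne = estimate_ne(theta, config$mu)$ne,
        n_windows = nrow(w))
    }
    summary$diversity <- div
  }

  if ("fst" %in% stages) {
    pairs <- utils::combn(seq_along(pop_names), 2, simplify = FALSE)
    fst_mat <- matrix(0, length(pop_names), length(pop_names),
                      dimnames = list(pop_names, pop_names))
    fst_sum <- list()
    for (pr in pairs) {
      p1 <- pr[1]; p2 <- pr[2]
      lab <- paste0(pop_names[p1], "_vs_", pop_names[p2])
      w <- window_fst(sync$counts[[p1]], sync$counts[[p2]], sync$pos,
                      sync$chrom, window_size = config$window_size,
                      min_count = config$min_count_fst,
                      min_depth = config$min_depth_fst,
                      max_depth1 = bounds[[p1]]$max,
                      max_depth2 = bounds[[p2]]$max,
                      min_covered_fraction = config$min_covered_fraction)
      wv <- w[!is.na(fst)]
      z <- withCallingHandlers(
        zfst_outliers(wv$fst, config$outlier_q, 1 - config$outlier_q),
        warning = function(w) invokeRestart("muffleWarning"))
      wv[, `:=`(z_fst = z$z_fst, outlier = z$outlier)]
      .write_table(wv, file.path(config$out_dir,
                                 sprintf("fst_windows_%s.tsv", lab)),
                   "1-based closed")
      bed <- wv[outlier != "none",
                .(chrom, start = start - 1L, end, name = outlier)]
      data.table::fwrite(bed,
                         file.path(config$out_dir,
                                   sprintf("fst_outliers_%s.bed", lab)),
                         sep = "\t", col.names = FALSE)
      gf <- gene_fst(sync$counts[[p1]], sync$counts[[p2]], sync$pos, genes,
                     min_count = config$min_count_fst,
                     min_depth = config$min_depth_fst,
                     max_depth1 = bounds[[p1]]$max,
                     max_depth2 = bounds[[p2]]$max)
      # SNP-level exact tests within gene bodies
      in_gene <- rep(FALSE, length(sync$pos))
      for (k in seq_len(nrow(genes)))
        in_gene[sync$pos >= genes$start[k] & sync$pos <= genes$end[k]] <- TRUE
      comb <- sync$counts[[p1]] + sync$counts[[p2]]
      minor <- rowSums(comb) - apply(comb, 1, max)
      test_i <- which(in_gene & minor >= config$min_count_fst)
      if (length(test_i)) {
        ft <- snp_fisher_bh(sync$counts[[p1]][test_i, , drop = FALSE],
                            sync$counts[[p2]][test_i, , drop = FALSE])
        snp_pos <- sync$pos[test_i]
        snp_sig <- ft$significant
      } else {
        snp_pos <- integer(0); snp_sig <- logical(0)
      }
      cand <- candidate_genes(genes, wv, gf, snp_pos, snp_sig,
                              upper_q = 1 - config$outlier_q)
      .write_table(cand, file.path(config$out_dir,
                                   sprintf("candidates_%s.tsv", lab)),
                   "1-based closed")
      gw <- mean(wv$fst)
      fst_mat[p1, p2] <- fst_mat[p2, p1] <- gw
      fst_sum[[lab]] <- list(mean_window_fst = gw,
                             n_windows = nrow(wv),
                             n_outlier_high = sum(wv$outlier == "high"),
                             n_candidate_genes = sum(cand$candidate))
    }
    summary$fst <- fst_sum
    if (length(pop_names) >= 3) {
      nwk <- nj_tree(fst_mat)
      writeLines(nwk, file.path(config$out_dir, "fst_nj_tree.nwk"))
      summary$nj_tree <- nwk
    }
  }

  if ("selection" %in% stages) {
    sel <- list()
    bins <- daf_bins(config$n_bins, config$daf_min, config$daf_max)
    for (p in seq_along(pop_names)) {
      pol <- polarized[[p]][!is.na(gene_id) &
                              degeneracy %in% c("zero_fold", "four_fold")]
      mk <- mk_counts(pol, bins = bins, genes = sort(unique(genes$gene_id)))
      gt <- data.table::copy(mk$genes)
      gt[, dos := dos(gt)]
      .write_table(gt, file.path(config$out_dir,
                                 sprintf("mk_dos_%s.tsv", pop_names[p])),
                   "n/a (per gene)")
      curve <- alpha_x(mk)
      afit <- try(fit_asymptotic_alpha(curve, mk = mk,
                                       n_boot = config$alpha_boot),
                  silent = TRUE)
      .write_table(curve, file.path(config$out_dir,
                                    sprintf("alpha_%s.tsv", pop_names[p])),
                   "n/a (per bin)")
      ds <- withCallingHandlers(
        dos_gene_sets(gt$dos, gt$gene_id),
        warning = function(w) invokeRestart("muffleWarning"))

      n_pool <- config$pops[[p]]$pool_size
      sfs_s <- build_sfs(pol[degeneracy == "four_fold"], n_pool,
                         "synonymous")
      sfs_n <- build_sfs(pol[degeneracy == "zero_fold"], n_pool,
                         "non_synonymous")
      ps <- project_sfs(sfs_s, config$sfs_project_n)
      pn <- project_sfs(sfs_n, config$sfs_project_n)
      sfs_dt <- data.table::data.table(
        class = rep(c("synonymous", "non_synonymous"),
                    each = config$sfs_project_n - 1L),
        i = rep(seq_len(config$sfs_project_n - 1L), 2),
        count = c(as.numeric(ps$counts), as.numeric(pn$counts)))
      .write_table(sfs_dt, file.path(config$out_dir,
                                     sprintf("sfs_%s.tsv", pop_names[p])),
                   "n/a (spectrum)")
      dfe <- try(fit_gamma_dfe(ps, pn, model = "del",
                               n_boot = config$dfe_boot), silent = TRUE)
      dfe_ok <- !inherits(dfe, "try-error")
      if (dfe_ok) {
        jsonlite::write_json(
          list(model = dfe$model, shape = dfe$shape, mean_S = dfe$mean_S,
               theta_syn = dfe$theta_syn, theta_nonsyn = dfe$theta_nonsyn,
               logLik = dfe$logLik, AIC = dfe$AIC),
          file.path(config$out_dir, sprintf("dfe_%s.json", pop_names[p])),
          auto_unbox = TRUE, digits = NA)
      }
      sel[[pop_names[p]]] <- list(
        Dn = sum(mk$genes$Dn), Ds = sum(mk$genes$Ds),
        Pn = sum(mk$genes$Pn), Ps = sum(mk$genes$Ps),
        alpha_pooled = alpha_pooled(sum(mk$genes$Dn), sum(mk$genes$Ds),
                                    sum(mk$genes$Pn), sum(mk$genes$Ps)),
        alpha_asymptotic = if (!inherits(afit, "try-error"))
          afit$alpha_asymptotic else NA,
        median_dos = ds$median,
        n_genes_dos = sum(!is.na(gt$dos)),
        dfe_shape = if (dfe_ok) dfe$shape else NA,
        dfe_mean_S = if (dfe_ok) dfe$mean_S else NA)
    }
    summary$selection <- sel
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(summary)
}
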