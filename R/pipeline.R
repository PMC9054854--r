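#' Run the full local-ancestry methylation pipeline
#'
#' Orchestrates simulate -> variant QC -> ancestry features -> EWAS (race,
#' global ancestry, local ancestry) -> cis-meQTL scan on the LA-associated
#' CpGs -> clumping -> positional enrichment, writing each stage's tables
#' under `out_dir` together with a JSON manifest of parameters, counts and
#' the count-derived significance thresholds. Stages whose outputs already
#' exist with matching input hashes are skipped unless `force`.
#'
#' All thresholds in the manifest are Bonferroni thresholds recomputed
#' from the recorded counts at run time (alpha over CpGs tested, over
#' pairs tested, over ancestry-model meQTLs).
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param out_dir output directory.
#' @param ewas_alpha epigenome-wide significance cutoff (default 1.16e-7;
#'   with simulated cohorts of a few hundred CpGs a Bonferroni cutoff at
#'   `0.05 / n_cpgs` is often more appropriate — pass it explicitly).
#' @param n_control_pcs,n_residual_pcs principal components adjusted in
#'   the association models (defaults 30 and 5; truncated to the control
#'   matrix rank).
#' @param window_bp cis window (total span) for the meQTL scan.
#' @param alpha family-wise alpha for count-derived thresholds.
#' @param force rerun all stages even when cached outputs match.
#' @return the manifest list, invisibly; all stage outputs are files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, ewas_alpha = 1.16e-7,
                         n_control_pcs = 30, n_residual_pcs = 5,
                         window_bp = 1e6, alpha = 0.05, force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(version = as.character(utils::packageVersion("admixmeth")),
                   seed = config$seed, stages = list())
  prev <- if (file.exists(manifest_path) && !force)
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL) else NULL
  save_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)

  stage <- function(name, inputs, outputs, params, fun) {
    hash <- unname(tools::md5sum(inputs[file.exists(inputs)]))
    key <- paste(c(hash, vapply(params, format, character(1))),
                 collapse = "|")
    cached <- !is.null(prev) && !is.null(prev$stages[[name]]) &&
      identical(prev$stages[[name]]$hash, key) && all(file.exists(outputs))
    info <- if (cached) {
      message("[", name, "] cached")
      prev$stages[[name]]
    } else {
      message("[", name, "] running")
      res <- tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(error = conditionMessage(e))
        save_manifest()
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      c(list(hash = key, params = params), res)
    }
    manifest$stages[[name]] <<- info
    save_manifest()
    invisible(info)
  }

  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             msp = file.path(out_dir, "local_ancestry.msp.tsv"),
             methylation = file.path(out_dir, "methylation.tsv"),
             control = file.path(out_dir, "control_probes.tsv"),
             covariates = file.path(out_dir, "covariates.tsv"),
             cpgs = file.path(out_dir, "cpg_manifest.tsv"),
             truth = file.path(out_dir, "truth.json"))

  stage("simulate", character(0), paths,
        list(seed = config$seed, n = config$n_individuals,
             n_cpgs = config$n_cpgs),
        function() {
          cohort <- simulate_cohort(config)
          write_cohort(cohort, out_dir)
          list(counts = list(n_individuals = config$n_individuals,
                             n_snps = nrow(cohort$panel$snps),
                             n_cpgs = nrow(cohort$panel$cpgs)))
        })

  # stages below share in-memory state; recompute it cheaply from files
  vcf <- read_phased_vcf(paths["vcf"])
  msp <- read_msp(paths["msp"])
  M <- read_matrix_tsv(paths["methylation"])
  ctrl <- read_matrix_tsv(paths["control"])
  covariates <- as.data.frame(data.table::fread(paths["covariates"]))
  cpgs <- as.data.frame(data.table::fread(paths["cpgs"]))

  qc_path <- file.path(out_dir, "variant_qc.tsv")
  stage("qc", unname(paths["vcf"]), qc_path,
        list(maf = 0.01, miss = 0.05, hwe = 1e-6),
        function() {
          dosage <- vcf$alleles[, 1, ] + vcf$alleles[, 2, ]
          colnames(dosage) <- vcf$snps$snp_id
          qc <- filter_variants(dosage, alleles = vcf$snps)
          data.table::fwrite(qc$report, qc_path, sep = "\t")
          list(counts = list(n_variants = ncol(dosage),
                             n_pass = sum(qc$keep)))
        })
  qc_report <- as.data.frame(data.table::fread(qc_path))
  keep <- qc_report$pass

  la_path <- file.path(out_dir, "local_ancestry_cpg.tsv")
  ga_path <- file.path(out_dir, "global_ancestry.tsv")
  stage("features", unname(c(paths["msp"], paths["cpgs"], qc_path)),
        c(la_path, ga_path),
        list(window_bp = window_bp),
        function() {
          afr <- msp$ancestry[, 1, ] + msp$ancestry[, 2, ]
          rownames(afr) <- msp$individuals
          la <- la_matrix(afr[, keep, drop = FALSE],
                          vcf$snps[keep, ], cpgs, window_bp)
          ga <- global_from_local(afr, scale = 2)
          write_matrix_tsv(t(la), la_path, "cpg_id")
          data.table::fwrite(data.frame(id = msp$individuals, global_afr = ga),
                             ga_path, sep = "\t")
          list(counts = list(n_cpgs_with_la = sum(colSums(!is.na(la)) > 0)))
        })
  la <- t(read_matrix_tsv(la_path))
  ga <- as.data.frame(data.table::fread(ga_path))$global_afr

  cov_cols <- c("age", "smoker", "log10_peth", "adherence", "log10_vl",
                "wbc", "cd4", "cd8", "gran", "nk", "bcell", "mono")
  cpcs <- control_probe_pcs(ctrl, k = min(n_control_pcs, nrow(ctrl) - 1,
                                          ncol(ctrl) - 1))
  base_X <- function(rows, extra = NULL) {
    X <- cbind(intercept = 1, as.matrix(covariates[rows, cov_cols]),
               cpcs[rows, , drop = FALSE])
    if (!is.null(extra)) X <- cbind(X, extra)
    X
  }
  aa <- covariates$race == 1

  ewas_stage <- function(name, rows, ancestry, extra_cov = NULL) {
    out_path <- file.path(out_dir, paste0("ewas_", name, ".tsv"))
    stage(paste0("ewas_", name),
          unname(c(paths["methylation"], paths["covariates"], la_path)),
          out_path,
          list(alpha = ewas_alpha, k_resid = n_residual_pcs),
          function() {
            X0 <- base_X(rows, extra_cov)
            rpcs <- stage1_residual_pcs(M[, rows, drop = FALSE], X0,
                                        k = n_residual_pcs)
            res <- run_ewas(M[, rows, drop = FALSE],
                            ancestry, cbind(X0, rpcs), alpha = ewas_alpha)
            data.table::fwrite(cbind(res,
                                     chrom = cpgs$chrom, pos = cpgs$pos),
                               out_path, sep = "\t")
            list(lambda = attr(res, "lambda"),
                 counts = list(n_cpgs = nrow(res),
                               n_significant = sum(res$significant)),
                 thresholds = list(
                   discovery = ewas_alpha,
                   replication = bonferroni_threshold(
                     alpha, max(1, sum(res$significant)))))
          })
    as.data.frame(data.table::fread(out_path))
  }

  ewas_race <- ewas_stage("race", rep(TRUE, nrow(covariates)),
                          covariates$race)
  ewas_ga <- ewas_stage("ga", aa, ga[aa])
  ewas_la <- ewas_stage("la", aa, la[aa, , drop = FALSE],
                        extra_cov = cbind(ga = ga[aa]))

  meqtl_path <- file.path(out_dir, "meqtl.tsv")
  clump_path <- file.path(out_dir, "clumps.tsv")
  enrich_path <- file.path(out_dir, "enrichment.tsv")
  sig_idx <- which(ewas_la$significant)
  dosage <- vcf$alleles[, 1, ] + vcf$alleles[, 2, ]
  colnames(dosage) <- vcf$snps$snp_id

  stage("meqtl", unname(c(paths["vcf"], paths["methylation"])), meqtl_path,
        list(window_bp = window_bp, alpha = alpha),
        function() {
          if (length(sig_idx) == 0) {
            data.table::fwrite(data.frame(), meqtl_path, sep = "\t")
            return(list(counts = list(n_pairs = 0, n_meqtl_anc = 0,
                                      n_meqtl_conv = 0)))
          }
          anc1 <- msp$ancestry[aa, 1, keep]; anc2 <- msp$ancestry[aa, 2, keep]
          al1 <- vcf$alleles[aa, 1, keep]; al2 <- vcf$alleles[aa, 2, keep]
          dec <- list(afr = al1 * (anc1 == 1L) + al2 * (anc2 == 1L),
                      eur = al1 * (anc1 == 0L) + al2 * (anc2 == 0L))
          dec$total <- dec$afr + dec$eur
          sc <- cis_scan(M[sig_idx, aa, drop = FALSE], cpgs[sig_idx, ],
                         vcf$snps[keep, ], dec,
                         la[aa, sig_idx, drop = FALSE],
                         base_X(aa, cbind(ga = ga[aa])),
                         window_bp = window_bp, alpha = alpha)
          data.table::fwrite(sc$records, meqtl_path, sep = "\t")
          list(counts = list(n_pairs = sc$n_pairs,
                             n_meqtl_conv = sc$n_meqtl_conv,
                             n_meqtl_anc = sc$n_meqtl_anc,
                             n_diff = sum(sc$records$sig_diff)),
               thresholds = list(meqtl = sc$meqtl_threshold,
                                 bdiff = sc$bdiff_threshold))
        })

  stage("clump", meqtl_path, clump_path, list(r2 = 0.01),
        function() {
          recs <- tryCatch(as.data.frame(data.table::fread(meqtl_path)),
                           error = function(e) NULL)
          if (is.null(recs) || nrow(recs) == 0 || !any(recs$sig_anc)) {
            data.table::fwrite(data.frame(), clump_path, sep = "\t")
            return(list(counts = list(n_clumps = 0)))
          }
          cl <- clump_scan(recs, dosage[aa, , drop = FALSE])
          data.table::fwrite(cl, clump_path, sep = "\t")
          list(counts = list(n_clumps = nrow(cl)))
        })

  stage("enrich", unname(paths["cpgs"]), enrich_path, list(fdr = 0.05),
        function() {
          if (length(sig_idx) == 0) {
            data.table::fwrite(data.frame(), enrich_path, sep = "\t")
            return(list(counts = list(n_annotations = 0)))
          }
          ann_cols <- setdiff(names(cpgs), c("cpg_id", "chrom", "pos"))
          enr <- annotation_enrichment(cpgs$cpg_id[sig_idx], cpgs$cpg_id,
                                       cpgs[, c("cpg_id", ann_cols)])
          data.table::fwrite(enr, enrich_path, sep = "\t")
          list(counts = list(n_annotations = nrow(enr),
                             n_significant = sum(enr$significant)))
        })

  invisible(manifest)
}
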