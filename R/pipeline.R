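#' Full-run configuration
#'
#' Bundles every stage's parameters with the package defaults: QC at call
#' rate >= 0.95 and MAF >= 0.05, the standard ROH criteria, the LD bin
#' scheme to 5 Mb and a genome-average recombination rate of 1 cM/Mb.
#'
#' @param ped_path,map_path input PLINK text files (ignored when
#'   \code{simulate} is given).
#' @param simulate optional \code{\link{sim_config}}; when present the input
#'   dataset is simulated instead of read.
#' @param qc a \code{\link{qc_params}}.
#' @param roh a \code{\link{roh_params}}.
#' @param max_dist_mb LD profile reach in Mb.
#' @param cm_per_mb genome-average recombination rate.
#' @param pca_k number of principal components.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed recorded in the manifest and applied before any
#'   stochastic stage.
#' @return a \code{run_config} list.
#' @export
run_config <- function(ped_path = NULL, map_path = NULL, simulate = NULL,
                       qc = qc_params(), roh = roh_params(),
                       max_dist_mb = 5, cm_per_mb = 1, pca_k = 10L,
                       out_dir = "breeddiv_out", seed = 1L) {
  if (is.null(simulate) && (is.null(ped_path) || is.null(map_path)))
    stop("either ped_path+map_path or a simulate config is required")
  structure(list(ped_path = ped_path, map_path = map_path,
                 simulate = simulate, qc = qc, roh = roh,
                 max_dist_mb = max_dist_mb, cm_per_mb = cm_per_mb,
                 pca_k = pca_k, out_dir = out_dir, seed = seed),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete analysis pipeline
#'
#' Stages, in dependency order: input (read or simulate), QC, map summary,
#' diversity table with LD-based current Ne (table1.tsv), ROH summary
#' (table2.tsv), LD profiles and Ne trajectories (ld_profiles.tsv,
#' ne_trajectories.tsv), PCA scores (pca_scores.tsv), pairwise F_ST /
#' Tajima-Nei matrix (table3.tsv: F_ST lower triangle, distance upper) and
#' the NJ tree (tree.nwk), plus a JSON run manifest. Any stage error aborts
#' with the stage name attached.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_all <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[breeddiv] ", sprintf(...))
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(force(expr),
             error = function(e) stop(sprintf("stage '%s' failed: %s",
                                              name, conditionMessage(e)),
                                      call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  p <- function(f) file.path(config$out_dir, f)

  ds_raw <- stage("input", {
    if (!is.null(config$simulate)) simulate_breeds(config$simulate)$dataset
    else read_plink(config$ped_path, config$map_path)
  })
  ds <- stage("qc", apply_qc(ds_raw, config$qc))
  write_tsv(qc_removals(ds), p("qc_removals.tsv"))
  mapsum <- stage("map_summary", summarize_map(ds))
  write_tsv(mapsum, p("map_summary.tsv"))

  profiles <- stage("ld", ld_profiles(ds, config$max_dist_mb))
  ld_tab <- do.call(rbind, lapply(profiles, function(pr)
    cbind(breed = pr$breed, pr$bins)))
  write_tsv(ld_tab, p("ld_profiles.tsv"))
  ne_traj <- do.call(rbind, lapply(profiles, function(pr) {
    tr <- past_ne_trajectory(pr, config$cm_per_mb)
    if (nrow(tr)) cbind(breed = pr$breed, tr) else NULL
  }))
  write_tsv(ne_traj, p("ne_trajectories.tsv"))

  div <- stage("diversity", diversity_table(ds))
  div$ne <- vapply(div$breed, function(b)
    tryCatch(current_ne(profiles[[b]], config$cm_per_mb),
             error = function(e) NA_real_), 0)
  write_tsv(div, p("table1.tsv"))

  roh_tab <- stage("roh", breed_roh_table(ds, config$roh))
  write_tsv(roh_tab, p("table2.tsv"))
  roh_segs <- stage("roh_segments", do.call(rbind, lapply(
    ds$samples$sample_id, function(s) detect_roh(ds, s, config$roh))))
  write_tsv(roh_segs, p("roh_segments.tsv"))

  pca <- stage("pca", genotype_pca(ds, config$pca_k))
  write_tsv(cbind(pca$samples, as.data.frame(pca$scores)),
            p("pca_scores.tsv"))
  write_tsv(data.frame(component = seq_along(pca$variance_fractions),
                       variance_fraction = pca$variance_fractions),
            p("pca_eigenvalues.tsv"))

  tab3 <- NULL; tree <- NULL
  if (length(breeds(ds)) >= 2L) {
    dmx <- stage("differentiation", distance_matrix(ds))
    tab3 <- dmx$fst
    tab3[upper.tri(tab3)] <- dmx$tajima_nei[upper.tri(tab3)]
    write_tsv(data.frame(breed = rownames(tab3), tab3, check.names = FALSE),
              p("table3.tsv"))
    if (length(breeds(ds)) >= 3L) {
      tree <- stage("nj", nj_tree(dmx$tajima_nei))
      write_newick(tree, p("tree.nwk"))
    }
  }

  manifest <- list(
    package = "breeddiv",
    version = as.character(utils::packageVersion("breeddiv")),
    seed = config$seed,
    parameters = list(qc = unclass(config$qc), roh = unclass(config$roh),
                      max_dist_mb = config$max_dist_mb,
                      cm_per_mb = config$cm_per_mb, pca_k = config$pca_k),
    inputs = if (is.null(config$ped_path)) "simulated" else
      as.list(tools::md5sum(c(config$ped_path, config$map_path))),
    n_samples = n_samples(ds), n_snps_post_qc = n_snps(ds),
    n_snps_input = n_snps(ds_raw))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done: outputs in %s", config$out_dir)
  invisible(list(dataset = ds, diversity = div, roh = roh_tab,
                 profiles = profiles, pca = pca, fst_tn = tab3, tree = tree,
                 out_dir = config$out_dir))
}

#' Command-line interface
#'
#' Subcommands: \code{qc}, \code{diversity}, \code{roh}, \code{ld},
#' \code{ne}, \code{fst}, \code{tree}, \code{pca}, \code{simulate},
#' \code{all}. Each maps onto the corresponding module function; flags
#' mirror \code{\link{run_config}} fields. Unknown subcommands or missing
#' inputs exit non-zero with a usage message. Installed alongside the
#' package as \code{inst/cli/breeddiv}.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
breeddiv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: breeddiv <qc|diversity|roh|ld|ne|fst|tree|pca|simulate|all> [options]",
    "  common options: --ped PATH --map PATH --out DIR --seed INT",
    "  roh: --min-snps --min-kb --max-gap-kb --max-het --max-missing",
    "  qc: --call-rate --maf | ld/ne: --cm-per-mb --max-dist-mb",
    "  simulate/all: --breeds N --n INT --gens INT --snps-per-chrom INT",
    "                --chroms INT --chrom-mb NUM --samples INT", sep = "\n")
  if (length(args) < 1L || !args[1] %in%
      c("qc", "diversity", "roh", "ld", "ne", "fst", "tree", "pca",
        "simulate", "all")) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  spec <- list(
    optparse::make_option("--ped", type = "character", default = NULL),
    optparse::make_option("--map", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "breeddiv_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--call-rate", type = "double", default = 0.95,
                          dest = "call_rate"),
    optparse::make_option("--maf", type = "double", default = 0.05),
    optparse::make_option("--min-snps", type = "integer", default = 40L,
                          dest = "min_snps"),
    optparse::make_option("--min-kb", type = "double", default = 1000,
                          dest = "min_kb"),
    optparse::make_option("--max-gap-kb", type = "double", default = 1000,
                          dest = "max_gap_kb"),
    optparse::make_option("--max-het", type = "integer", default = 1L,
                          dest = "max_het"),
    optparse::make_option("--max-missing", type = "integer", default = 5L,
                          dest = "max_missing"),
    optparse::make_option("--cm-per-mb", type = "double", default = 1,
                          dest = "cm_per_mb"),
    optparse::make_option("--max-dist-mb", type = "double", default = 5,
                          dest = "max_dist_mb"),
    optparse::make_option("--r2", type = "double", default = NULL),
    optparse::make_option("--breeds", type = "integer", default = 3L),
    optparse::make_option("--n", type = "integer", default = 50L),
    optparse::make_option("--gens", type = "integer", default = 30L),
    optparse::make_option("--snps-per-chrom", type = "integer", default = 300L,
                          dest = "snps_per_chrom"),
    optparse::make_option("--chroms", type = "integer", default = 3L),
    optparse::make_option("--chrom-mb", type = "double", default = 100,
                          dest = "chrom_mb"),
    optparse::make_option("--samples", type = "integer", default = 20L))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args[-1]),
    error = function(e) { message("argument error: ", conditionMessage(e),
                                  "\n", usage); NULL })
  if (is.null(opt)) return(invisible(1L))

  needs_dataset <- cmd %in% c("qc", "diversity", "roh", "ld", "fst",
                              "tree", "pca")
  if (needs_dataset && (is.null(opt$ped) || is.null(opt$map))) {
    message("--ped and --map are required for '", cmd, "'\n", usage)
    return(invisible(1L))
  }
  qc <- qc_params(opt$call_rate, opt$maf)
  rohp <- roh_params(opt$min_snps, opt$min_kb, max_gap_kb = opt$max_gap_kb,
                     max_het = opt$max_het, max_missing = opt$max_missing)
  if (cmd != "ne")   # 'ne' prints to stdout and writes nothing
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  mk_sim <- function() sim_config(
    genome = sim_genome(opt$chroms, opt$chrom_mb, opt$snps_per_chrom,
                        opt$cm_per_mb),
    breeds = data.frame(breed = sprintf("Breed%02d", seq_len(opt$breeds)),
                        N = opt$n, generations = opt$gens),
    samples_per_breed = opt$samples, seed = opt$seed)
  load_ds <- function() apply_qc(read_plink(opt$ped, opt$map), qc)

  status <- tryCatch({
    switch(cmd,
      ne = {
        if (is.null(opt$r2)) stop("--r2 is required for 'ne'")
        cat(sprintf("%.6g\n", ne_from_r2(opt$r2, opt$cm_per_mb / 100)))
      },
      simulate = {
        sim <- simulate_breeds(mk_sim())
        write_plink(sim$dataset, file.path(opt$out, "sim.ped"),
                    file.path(opt$out, "sim.map"))
        write_tsv(data.frame(breed = names(sim$truth$expected_fst),
                             expected_fst = sim$truth$expected_fst,
                             true_ne = sim$truth$true_ne),
                  file.path(opt$out, "sim_truth.tsv"))
      },
      all = {
        cfg <- if (is.null(opt$ped)) run_config(simulate = mk_sim(),
                                                qc = qc, roh = rohp,
                                                cm_per_mb = opt$cm_per_mb,
                                                out_dir = opt$out,
                                                seed = opt$seed)
               else run_config(opt$ped, opt$map, qc = qc, roh = rohp,
                               cm_per_mb = opt$cm_per_mb, out_dir = opt$out,
                               seed = opt$seed)
        run_all(cfg)
      },
      { # dataset-consuming subcommands
        ds <- load_ds()
        switch(cmd,
          qc = { write_tsv(qc_removals(ds), file.path(opt$out, "qc_removals.tsv"))
                 write_plink(ds, file.path(opt$out, "qc.ped"),
                             file.path(opt$out, "qc.map")) },
          diversity = write_tsv(diversity_table(ds),
                                file.path(opt$out, "table1.tsv")),
          roh = { write_tsv(breed_roh_table(ds, rohp),
                            file.path(opt$out, "table2.tsv")) },
          ld = { profs <- ld_profiles(ds, opt$max_dist_mb)
                 write_tsv(do.call(rbind, lapply(profs, function(pr)
                   cbind(breed = pr$breed, pr$bins))),
                   file.path(opt$out, "ld_profiles.tsv")) },
          fst = { dmx <- distance_matrix(ds)
                  write_tsv(data.frame(breed = rownames(dmx$fst), dmx$fst,
                                       check.names = FALSE),
                            file.path(opt$out, "fst.tsv")) },
          tree = write_newick(nj_tree(distance_matrix(ds)$tajima_nei),
                              file.path(opt$out, "tree.nwk")),
          pca = { res <- genotype_pca(ds)
                  write_tsv(cbind(res$samples, as.data.frame(res$scores)),
                            file.path(opt$out, "pca_scores.tsv")) })
      })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

#' Plot LD decay for one or more breeds
#'
#' Mean r2 against bin midpoint distance, one line per breed, on the current
#' graphics device.
#'
#' @param profiles list of \code{ld_profile} objects.
#' @param ... passed to \code{matplot}.
#' @return invisibly, the plotted matrix.
#' @export
plot_ld_decay <- function(profiles, ...) {
  x <- profiles[[1]]$bins$mid_mb
  y <- vapply(profiles, function(p) p$bins$mean_r2, numeric(length(x)))
  graphics::matplot(x, y, type = "l", lty = 1, xlab = "distance (Mb)",
                    ylab = expression(mean ~ r^2), ...)
  graphics::legend("topright", legend = vapply(profiles, `[[`, "", "breed"),
                   lty = 1, col = seq_along(profiles), cex = 0.7)
  invisible(y)
}

#' Scatter of the first two principal components, coloured by breed
#' @param pca a \code{pca_result}.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plot_pca <- function(pca, ...) {
  br <- factor(pca$samples$breed)
  graphics::plot(pca$scores[, 1], pca$scores[, 2], col = as.integer(br),
                 pch = 19, xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = levels(br), col = seq_along(levels(br)),
                   pch = 19, cex = 0.7)
  invisible(NULL)
}
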