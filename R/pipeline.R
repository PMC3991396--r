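# End-to-end orchestration: configuration with explicit defaults for every
# parameter the workflow leaves open, stage execution in dependency order,
# plain-text artifacts, and a run manifest with checksums.

#' Read / write GMT gene-set files
#'
#' Tab-separated GMT dialect: set name, description, member genes. Duplicate
#' set names and lines with fewer than two fields are errors (with the line
#' number).
#'
#' @param path File path.
#' @return `read_gmt`: named list of gene-id vectors (descriptions in the
#'   `descriptions` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), descriptions = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 2 fields")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every parameter the workflow leaves open has an explicit default here and
#' is echoed into the run manifest. Stages: preprocess, spectrum (CRA + CCM
#' + spectrum vectors), som, modules, gsea, minet.
#'
#' @param seed Master seed consumed by every randomized stage.
#' @param outdir Artifact directory.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, outdir = "macnet_out") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = c("preprocess", "spectrum", "som", "modules", "gsea", "minet"),
    preprocess = list(quantile_normalize = TRUE, background_quantile = 0.25,
                      min_margin = 0.5),
    spectrum = list(r_threshold = 0.85, top_n = 1000, k = 10,
                    linkage = "average", layout_iterations = 500,
                    mcl_inflation = 2),
    som = list(grid_w = 10, grid_h = 10, epochs = 50, metaclusters = 10,
               marker_margin = 1),
    modules = list(powers = c(1:10, 12, 14, 16, 18, 20), target_r2 = 0.85,
                   min_size = 20, cut_height = 0.995, merge_r = 0.8),
    gsea = list(n_perm = 1000, metric = "signal2noise", weight = 1,
                nes_min = 1, p_max = 0.05),
    minet = list(alpha = 1e-7, n_null = 10000, correction = "bonferroni",
                 dpi_tolerance = 0.1, hub_fraction = 0.1, top_tfs = 5)
  ), class = "pipeline_config")
}

#' Load a configuration from YAML or JSON
#'
#' Values present in the file override the defaults; everything else keeps
#' its default so the manifest always records a complete parameter set.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Bundled demonstration dataset
#'
#' A 200-gene x 60-sample synthetic scenario with six conditions (baseline
#' plus five stimuli), six planted 30-gene modules -- including an
#' antagonistic M1-like/M2-like pair sharing one axis, which unsigned
#' coexpression analysis correctly reports as a single bipolar module --
#' and three exclusive markers. Used by the end-to-end examples and tests.
#'
#' @param seed Integer seed, default 421.
#' @return An `expr_set` with ground truth attached.
#' @export
demo_dataset <- function(seed = 421L) {
  conds <- c("IFNg", "IL4", "TPP", "GC", "PA")
  design <- make_design(6, 10, baseline_name = "Mb", seed = seed,
                        condition_names = conds)
  gene_block <- function(pre, n) sprintf("%s%03d", pre, seq_len(n))
  modules <- list(
    list(genes = gene_block("m1g", 30), effects = c(IFNg = 2, IL4 = -2)),
    list(genes = gene_block("m2g", 30), effects = c(IL4 = 2, IFNg = -2)),
    list(genes = gene_block("tpp", 30), effects = c(TPP = 2)),
    list(genes = gene_block("gcg", 30), effects = c(GC = 2)),
    list(genes = gene_block("pag", 30), effects = c(PA = 2)),
    list(genes = gene_block("com", 30),
         effects = c(IFNg = 2, IL4 = 2, TPP = 2, GC = 2, PA = 2))
  )
  markers <- list(
    list(gene = "mk_ifng", condition = "IFNg", effect = 3),
    list(gene = "mk_tpp", condition = "TPP", effect = 3),
    list(gene = "mk_gc", condition = "GC", effect = 3)
  )
  st <- planted_structure(modules = modules, markers = markers,
                          noise_sd = 0.5, baseline_mean = 8, gene_mean_sd = 2)
  simulate_expression(design, st, n_background_genes = 17, seed = seed)
}

#' Run the full workflow
#'
#' Executes the enabled stages in dependency order (preprocess -> spectrum /
#' som -> modules -> gsea -> minet), writes all quantitative artifacts as
#' plain text under `config$outdir`, and returns a run manifest (config
#' snapshot, package version, per-artifact md5 checksums, warnings). Stage
#' failures abort with the stage name.
#'
#' @param x An `expr_set` (or NULL to use `expr_path`/`design_path`).
#' @param config A `pipeline_config` (see [default_config()]).
#' @param expr_path,design_path Optional TSV inputs read when `x` is NULL.
#' @param tf_list Optional TF gene ids for the TF-network stages.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(x = NULL, config = default_config(),
                         expr_path = NULL, design_path = NULL,
                         tf_list = NULL) {
  if (is.null(x)) {
    if (is.null(expr_path) || is.null(design_path))
      stop("provide either an expr_set or expr_path + design_path")
    x <- read_expr_set(expr_path, design_path)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  artifacts <- character()
  keep <- function(paths) artifacts <<- c(artifacts, paths)
  stage_on <- function(s) s %in% config$stages
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  design <- x$design
  baseline <- unique(as.character(design$condition[design$is_baseline]))

  expressed <- rownames(x$values)
  if (stage_on("preprocess")) run_stage("preprocess", function() {
    if (isTRUE(config$preprocess$quantile_normalize)) x <<- quantile_normalize(x)
    det <- detection_filter(x, design,
                            config$preprocess$background_quantile,
                            config$preprocess$min_margin)
    expressed <<- det$expressed_genes
    if (!length(expressed)) {
      note("detection filter removed all genes; keeping full matrix")
      expressed <<- rownames(x$values)
    }
    utils::write.table(
      data.frame(gene = rownames(det$detected), det$detected,
                 check.names = FALSE),
      file.path(outdir, "detection.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "detection.tsv"))
    av <- anova_screen(x, design)
    utils::write.table(av, file.path(outdir, "anova_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "anova_screen.tsv"))
  })

  graph <- NULL; ccm <- NULL; vectors <- NULL
  if (stage_on("spectrum")) run_stage("spectrum", function() {
    graph <<- correlation_graph(x, genes = expressed,
                                r_threshold = config$spectrum$r_threshold)
    clusters <- mcl_cluster(graph, inflation = config$spectrum$mcl_inflation)
    graph <<- layout_3d(graph, iterations = config$spectrum$layout_iterations,
                        seed = config$seed)
    keep(write_sample_graph(graph,
                            file.path(outdir, "sample_edges.tsv"),
                            file.path(outdir, "sample_graph.graphml"),
                            file.path(outdir, "sample_layout.tsv")))
    utils::write.table(
      data.frame(sample = names(clusters), cluster = as.integer(clusters)),
      file.path(outdir, "sample_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "sample_clusters.tsv"))
    k <- min(config$spectrum$k, length(unique(design$condition)))
    ccm <<- condition_ccm(x, design, top_n = config$spectrum$top_n, k = k,
                          linkage = config$spectrum$linkage)
    keep(write_ccm(ccm, file.path(outdir, "ccm.tsv"),
                   file.path(outdir, "ccm_dendrogram.nwk")))
    vectors <<- spectrum_vectors(graph, design, ccm)
    utils::write.table(vectors, file.path(outdir, "spectrum_vectors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(vectors, file.path(outdir, "spectrum_vectors.json"),
                         auto_unbox = TRUE, digits = NA)
    keep(file.path(outdir, c("spectrum_vectors.tsv", "spectrum_vectors.json")))
  })

  if (stage_on("som")) run_stage("som", function() {
    prof <- condition_profiles(x, design)
    prof <- prof[rownames(prof) %in% expressed, , drop = FALSE]
    map <- som_fit(prof, config$som$grid_w, config$som$grid_h,
                   config$som$epochs, seed = config$seed)
    map <- som_metaclusters(map, min(config$som$metaclusters,
                                     nrow(map$codebooks)))
    utils::write.table(
      data.frame(gene = names(map$bmu), unit = as.integer(map$bmu),
                 metacluster = as.integer(map$gene_clusters)),
      file.path(outdir, "som_assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "som_assignments.tsv"))
    mk <- exclusive_markers(x, design, margin_min = config$som$marker_margin)
    utils::write.table(mk, file.path(outdir, "exclusive_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "exclusive_markers.tsv"))
  })

  mods <- NULL
  if (stage_on("modules")) run_stage("modules", function() {
    sub <- x$values[expressed, , drop = FALSE]
    power <- pick_soft_threshold(sub, powers = config$modules$powers,
                                 target_r2 = config$modules$target_r2)
    adj <- adjacency_matrix(sub, power)
    tom <- topological_overlap(adj)
    mods <<- detect_modules(tom, sub, min_size = config$modules$min_size,
                            cut_height = config$modules$cut_height,
                            merge_r = config$modules$merge_r)
    keep(modules_to_gmt(mods$modules, file.path(outdir, "modules.gmt")))
    utils::write.table(
      data.frame(gene = names(mods$membership),
                 module = as.integer(mods$membership)),
      file.path(outdir, "module_membership.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "module_membership.tsv"))
    if (length(mods$modules)) {
      mt <- module_trait_correlation(mods$modules, design)
      utils::write.table(
        data.frame(module = rownames(mt$r), mt$r, check.names = FALSE),
        file.path(outdir, "module_trait_r.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      keep(file.path(outdir, "module_trait_r.tsv"))
    } else note("no coexpression modules detected")
    if (!is.null(tf_list) && length(mods$modules)) {
      ids <- vapply(mods$modules, `[[`, 1L, "id")
      tfnet <- tf_subnetwork_correlations(x, mods$membership, ids,
                                          intersect(tf_list, rownames(x$values)))
      utils::write.table(tfnet, file.path(outdir, "tf_module_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      keep(file.path(outdir, "tf_module_edges.tsv"))
    }
  })

  if (stage_on("gsea")) run_stage("gsea", function() {
    if (is.null(mods) || !length(mods$modules)) {
      note("gsea skipped: no modules available as gene sets")
      return(invisible())
    }
    sets <- setNames(lapply(mods$modules, `[[`, "genes"),
                     paste0("module", vapply(mods$modules, `[[`, 1L, "id")))
    contrasts <- setdiff(unique(as.character(design$condition)), baseline)
    res <- do.call(rbind, lapply(contrasts, function(cn) {
      r <- gsea_permutation(x, design, cn, baseline, sets,
                            n_perm = config$gsea$n_perm,
                            metric = config$gsea$metric,
                            p = config$gsea$weight, seed = config$seed)
      r$contrast <- cn
      r
    }))
    res <- volcano_table(res, config$gsea$nes_min, config$gsea$p_max)
    utils::write.table(res, file.path(outdir, "gsea_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    keep(file.path(outdir, "gsea_results.tsv"))
  })

  if (stage_on("minet")) run_stage("minet", function() {
    sub <- x$values[expressed, , drop = FALSE]
    cutoff <- mi_significance_threshold(sub, alpha = config$minet$alpha,
                                        n_null = config$minet$n_null,
                                        correction = config$minet$correction,
                                        seed = config$seed)
    net <- all_vs_all(sub, cutoff = as.numeric(cutoff))
    net <- dpi_prune(net, tolerance = config$minet$dpi_tolerance)
    if (nrow(net$edges)) {
      net <- extract_hubs(net, fraction = config$minet$hub_fraction)
    } else note("MI network empty after DPI; no hubs")
    keep(write_mi_network(net, file.path(outdir, "mi_edges.tsv"),
                          file.path(outdir, "mi_network.graphml"),
                          file.path(outdir, "mi_hubs.tsv")))
    if (!is.null(tf_list) && length(net$hubs)) {
      nb <- tf_neighborhoods(net, intersect(tf_list, net$nodes), x,
                             top_k = config$minet$top_tfs,
                             cluster_of = if (!is.null(ccm)) ccm$cluster_of)
      jsonlite::write_json(
        lapply(nb, function(e) list(tf = e$tf, avg_expr = e$avg_expr,
                                    neighbors = e$neighbors)),
        file.path(outdir, "tf_neighborhoods.json"),
        auto_unbox = TRUE, digits = NA)
      keep(file.path(outdir, "tf_neighborhoods.json"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("macnet")),
    config = unclass(config),
    n_genes = nrow(x$values), n_samples = ncol(x$values),
    n_expressed = length(expressed),
    checksums = {
      paths <- sort(unique(artifacts))
      cs <- tools::md5sum(paths)
      as.list(setNames(unname(cs), basename(paths)))
    },
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
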