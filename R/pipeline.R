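#' Validate and default a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with either
#' input paths (`counts`, `metadata`, optionally `tree`) or a `simulate`
#' block of [simulation_config()] arguments — never both. Remaining keys
#' receive the study defaults: rarefaction depth 70492, diversity orders
#' 0/1/2, 999 null randomizations, significance threshold 2. The `"reduced"`
#' profile (depth 5000, 99 randomizations) is intended for smoke tests and
#' quick exploration.
#'
#' @param config named list or path to a YAML file.
#' @return The fully defaulted config (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or a YAML file path")
  known <- c("counts", "metadata", "tree", "simulate", "profile",
             "rarefaction_depth", "orders", "variant", "null", "output_dir",
             "seed", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))

  profile <- config$profile %||% "paper"
  if (!profile %in% c("paper", "reduced")) stop("unknown profile: ", profile)
  defaults <- if (profile == "paper")
    list(rarefaction_depth = 70492, n_randomizations = 999)
  else
    list(rarefaction_depth = 5000, n_randomizations = 99)

  file_mode <- !is.null(config$counts) || !is.null(config$metadata)
  sim_mode <- !is.null(config$simulate)
  if (file_mode && sim_mode)
    stop("config must have either input paths or a simulate block, not both")
  if (!file_mode && !sim_mode)
    stop("config needs input paths (counts, metadata) or a simulate block")
  if (file_mode && (is.null(config$counts) || is.null(config$metadata)))
    stop("file mode needs both counts and metadata paths")

  config$profile <- profile
  config$rarefaction_depth <- config$rarefaction_depth %||% defaults$rarefaction_depth
  if (config$rarefaction_depth < 1) stop("rarefaction_depth must be positive")
  config$orders <- config$orders %||% c(0, 1, 2)
  if (any(config$orders < 0)) stop("diversity orders must be >= 0")
  config$variant <- config$variant %||% "local"
  config$seed <- config$seed %||% 1
  nm <- config$null %||% list()
  config$null <- null_config(
    n_randomizations = nm$n_randomizations %||% defaults$n_randomizations,
    threshold = nm$threshold %||% 2,
    pool_scope = nm$pool_scope %||% "all_samples",
    weighting = nm$weighting %||% "frequency_x_abundance",
    seed = child_seed(config$seed, "null_models"))
  config$output_dir <- config$output_dir %||% "hilldrift_output"
  if (sim_mode && !inherits(config$simulate, "simulation_config")) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% child_seed(config$seed, "simulate")
    config$simulate <- do.call(simulation_config, sim_args)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the full community-assembly analysis pipeline
#'
#' Mirrors the study workflow: load (or simulate) the count table, metadata
#' and tree; rarefy to even depth; compute Hill-number alpha-diversities
#' (`qTD`, `qPD`); all pairwise taxonomic and phylogenetic dissimilarities;
#' Raup-Crick and betaNTI standardized effect sizes along the successive and
#' between-reactor comparison series; time-decay fits per reactor and order;
#' and a PERMANOVA between the reactors. All outputs are written as TSV to
#' `output_dir` together with a manifest (parameters, seed, input checksums)
#' that suffices to reproduce every output byte for byte.
#'
#' @param config a [validate_config()]-compatible list or YAML path.
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- run_stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_study(config$simulate)
      paths <- list(counts = file.path(config$output_dir, "simulated_counts.tsv"),
                    metadata = file.path(config$output_dir, "simulated_metadata.tsv"),
                    tree = file.path(config$output_dir, "simulated_tree.nwk"))
      write_counts(sim$table, paths$counts)
      write_metadata(sim$metadata, paths$metadata)
      ape::write.tree(sim$tree, paths$tree)
      list(table = sim$table, metadata = sim$metadata, tree = sim$tree,
           paths = paths)
    } else {
      metadata <- read_metadata(config$metadata)
      table <- read_counts(config$counts, orientation = "auto",
                           metadata = metadata)
      check_samples_covered(table, metadata)
      tree <- if (!is.null(config$tree))
        read_newick(config$tree, require_tips = rownames(table))
      list(table = table, metadata = metadata, tree = tree,
           paths = config[c("counts", "metadata", "tree")])
    }
  })

  rarefied <- run_stage("rarefy", {
    tab <- rarefy(inputs$table, depth = config$rarefaction_depth,
                  seed = child_seed(config$seed, "rarefy"))
    md <- inputs$metadata[inputs$metadata$sample_id %in% colnames(tab), ]
    list(table = tab, metadata = md)
  })
  tab <- rarefied$table
  md <- rarefied$metadata
  distances <- if (!is.null(inputs$tree))
    run_stage("distances", patristic_distances(inputs$tree, rownames(tab)))

  alpha <- run_stage("alpha", alpha_table(tab, q = config$orders, distances))

  dissim <- run_stage("dissimilarity", {
    out <- dissimilarity_matrix(tab, q = config$orders, kind = "taxonomic",
                                variant = config$variant)
    if (!is.null(distances))
      out <- rbind(out, dissimilarity_matrix(tab, q = config$orders,
                                             kind = "phylogenetic",
                                             distances = distances,
                                             variant = config$variant))
    out
  })

  reactors <- sort(unique(md$reactor[md$role == "timepoint"]))
  series <- run_stage("series", {
    s <- lapply(reactors, function(r) {
      sr <- build_series(md, "successive", reactor = r)
      sr$series <- paste0("successive_", r)
      sr
    })
    if (length(reactors) == 2) {
      br <- build_series(md, "between_reactor", reactor = reactors)
      br$series <- "between_reactor"
      br$day <- NULL
      s <- c(s, list(br))
    }
    do.call(rbind, s)
  })

  ses <- run_stage("null_models", {
    out <- do.call(rbind, lapply(config$orders, function(qq)
      ses_series(tab, series, "qRC", q = qq, config = config$null)))
    if (!is.null(distances))
      out <- rbind(out, ses_series(tab, series, "betaNTI",
                                   distances = distances, config = config$null))
    out
  })

  timedecay <- run_stage("time_decay", {
    kinds <- c("taxonomic", if (!is.null(distances)) "phylogenetic")
    grid <- expand.grid(reactor = reactors, q = config$orders, kind = kinds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
      time_decay_rate(dissim, md, grid$reactor[i], q = grid$q[i],
                      kind = grid$kind[i])))
  })

  perm <- run_stage("permanova", {
    if (length(reactors) < 2) NULL else do.call(rbind, lapply(config$orders,
      function(qq) {
        rec <- dissim[dissim$q == qq & dissim$kind == "taxonomic", ]
        tp <- md$sample_id[md$role == "timepoint"]
        rec <- rec[rec$sample_a %in% tp & rec$sample_b %in% tp, ]
        m <- as_dissimilarity_matrix(rec)
        groups <- stats::setNames(md$reactor, md$sample_id)[rownames(m)]
        r <- permanova(m, groups,
                       n_permutations = config$null$n_randomizations,
                       seed = child_seed(config$seed, "permanova", qq))
        cbind(q = qq, r)
      }))
  })

  out_tsv <- function(x, name) {
    path <- file.path(config$output_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(alpha = out_tsv(alpha, "alpha.tsv"),
             dissimilarity = out_tsv(dissim, "dissimilarity.tsv"),
             ses = out_tsv(ses, "ses.tsv"),
             timedecay = out_tsv(timedecay, "timedecay.tsv"))
  if (!is.null(perm)) files["permanova"] <- out_tsv(perm, "permanova.tsv")

  manifest <- run_stage("manifest", {
    mf <- list(parameters = manifest_params(config),
               input_checksums = as.list(tools::md5sum(
                 unlist(inputs$paths[!vapply(inputs$paths, is.null, logical(1))]))),
               outputs = as.list(files))
    yaml::write_yaml(mf, file.path(config$output_dir, "manifest.yaml"))
    mf
  })

  invisible(list(table = tab, metadata = md, tree = inputs$tree,
                 alpha = alpha, dissimilarity = dissim, ses = ses,
                 timedecay = timedecay, permanova = perm,
                 manifest = manifest, files = files))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

manifest_params <- function(config) {
  sim <- config$simulate
  list(profile = config$profile,
       rarefaction_depth = config$rarefaction_depth,
       orders = config$orders,
       variant = config$variant,
       seed = config$seed,
       null = unclass(config$null),
       simulate = if (!is.null(sim)) unclass(sim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
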