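#' Write an analysis results bundle
#'
#' Writes tabular results as tab-delimited text, dendrograms as newick, and
#' a machine-readable JSON manifest recording the seed, configuration and
#' package version. Output is deterministic: two runs with the same inputs
#' produce byte-identical tables.
#'
#' @param results named list; data frames and matrices become `<name>.tsv`,
#'   `upgma_dendrogram` objects become `<name>.nwk`, scalar lists are
#'   embedded in the manifest under `summaries`.
#' @param dir output directory (created if needed).
#' @param seed,config metadata recorded in the manifest.
#' @return the manifest, invisibly; written as `manifest.json` in `dir`.
#' @export
write_results_bundle <- function(results = list(), dir, seed = NULL,
                                 config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  summaries <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "upgma_dendrogram")) {
      f <- file.path(dir, paste0(nm, ".nwk"))
      dendrogram_newick(x, f)
    } else if (inherits(x, "dist_matrix")) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write.table(x$distances, f, sep = "\t", quote = FALSE,
                  col.names = NA)
    } else if (is.data.frame(x) || is.matrix(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write.table(x, f, sep = "\t", quote = FALSE,
                  row.names = is.matrix(x) && !is.null(rownames(x)),
                  col.names = if (is.matrix(x) && !is.null(rownames(x))) NA
                              else TRUE)
    } else {
      summaries[[nm]] <- x
      next
    }
    files <- c(files, basename(f))
  }
  manifest <- list(package = "rsdnet",
                   version = as.character(utils::packageVersion("rsdnet")),
                   seed = seed, config = config, files = files,
                   summaries = summaries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Configuration for the full analysis pipeline
#'
#' @param input `"fixture"` (the packaged worked example), `"synthetic"`
#'   (a [generate_rsdb_like] draw), or a path to an edge-list CSV.
#' @param n_null_samples fixed-margin null samples (study scale uses 10000).
#' @param n_perm permutations for homophily and vector-fitting tests.
#' @param sampler `"curveball"` or `"sis"`.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it and the stage name, so toggling one stage leaves the others'
#'   randomness unchanged.
#' @param shared_pair_threshold report node pairs sharing at least this many
#'   neighbours.
#' @param canonical apply the curated synonym map when `input = "fixture"`.
#' @param stages character vector of stages to run, a subset of
#'   `c("stats", "null", "attributes", "ordination")`.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = "fixture", n_null_samples = 10000,
                       n_perm = 999, sampler = "curveball", seed = 1,
                       shared_pair_threshold = 10, canonical = TRUE,
                       stages = c("stats", "null", "attributes",
                                  "ordination")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(input = input, n_null_samples = n_null_samples,
                 n_perm = n_perm, sampler = sampler, seed = as.integer(seed),
                 shared_pair_threshold = shared_pair_threshold,
                 canonical = canonical, stages = stages),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Fields mirror the arguments of [run_config]; missing fields keep their
#' defaults. YAML files require the `yaml` package.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [run_config].
#' @export
run_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# Deterministic per-stage substream: master seed folded with a stable hash
# of the stage name, kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Run the full comparative analysis
#'
#' Executes, in order: input loading and canonicalization, observed network
#' statistics, fixed-margin null comparison, attribute analyses (category
#' counts, management scales, homophily) where attributes are available, and
#' ordination (distances, UPGMA, classical MDS, vector fitting). Results are
#' returned and, when `dir` is given, written as a bundle with a manifest.
#'
#' @param config a [run_config].
#' @param dir optional output directory for [write_results_bundle].
#' @return named list of stage outputs (`network`, `summary`, `comparison`,
#'   `category_counts_*`, `scale_proportions`, `homophily`, `distances`,
#'   `dendrogram`, `ordination`, `fitted_variables`, depending on input and
#'   stages); errors in a stage are reported with the stage name and partial
#'   results are kept.
#' @export
run_full_analysis <- function(config = run_config(), dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- list()
  attrs <- NULL; scheme <- NULL; blocks <- NULL

  if (identical(config$input, "fixture")) {
    fx <- load_table1_fixture(canonical = config$canonical)
    net <- fx$network
    attrs <- fx$shifts
  } else if (identical(config$input, "synthetic")) {
    syn <- generate_rsdb_like(stage_seed(config$seed, "synthetic"))
    net <- syn$network
    attrs <- syn$attributes
    scheme <- syn$scheme
    blocks <- syn$blocks
  } else {
    net <- read_bipartite_edge_list(config$input)
  }
  out$network <- net

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("stats" %in% config$stages) run_stage("stats", {
    out$summary <- network_summary(net)
    out$driver_summary <- driver_summary(net)
    out$shared_pairs <- shared_driver_pairs(
      net, "driver", threshold = config$shared_pair_threshold)
  })

  if ("null" %in% config$stages) run_stage("null", {
    set.seed(stage_seed(config$seed, "null"))
    ens <- build_null_ensemble(net, n_samples = config$n_null_samples,
                               method = config$sampler)
    out$null_statistics <- ens$statistics
    out$comparison <- compare_to_null(out$summary %||% network_summary(net),
                                      ens)
  })

  if ("attributes" %in% config$stages && !is.null(attrs)) {
    run_stage("attributes", {
      if (!is.null(scheme)) {
        out$category_counts_detailed <- category_counts(net, scheme,
                                                        "detailed")
        out$category_counts_broad <- category_counts(net, scheme, "broad")
      }
      if ("management_scale" %in% names(attrs)) {
        out$scale_proportions <- management_scale_proportions(net, attrs)
        out$scale_shares <- global_scale_shares(attrs)
        proj <- project_one_mode(net, "driver")
        da <- attrs[attrs$side == "driver", ]
        out$homophily <- attribute_homophily_test(
          proj, stats::setNames(da$management_scale, da$node_name),
          n_perm = config$n_perm,
          seed = stage_seed(config$seed, "homophily"))
      }
    })
  }

  if ("ordination" %in% config$stages) run_stage("ordination", {
    out$distances_shifts <- pairwise_distance(net, "shift", "sorensen_dice")
    out$distances_drivers <- pairwise_distance(net, "driver", "jaccard")
    out$dendrogram_drivers <- upgma_cluster(out$distances_drivers)
    out$dendrogram_shifts <- upgma_cluster(out$distances_shifts)
    out$ordination <- classical_mds(out$distances_shifts, k = 2)
    if (!is.null(blocks)) {
      sa <- attrs[attrs$side == "shift", ]
      rownames(sa) <- sa$node_name
      vars <- sa[, unlist(blocks), drop = FALSE]
      out$fitted_variables <- fit_variables(
        out$ordination, vars, n_perm = config$n_perm,
        seed = stage_seed(config$seed, "envfit"))
    }
  })

  if (!is.null(dir)) {
    writable <- c("comparison", "shared_pairs", "scale_proportions",
                  "category_counts_detailed", "category_counts_broad",
                  "fitted_variables", "null_statistics",
                  "dendrogram_drivers", "dendrogram_shifts")
    bundle <- out[intersect(writable, names(out))]
    bundle$summary <- out$summary
    bundle$coordinates <- if (!is.null(out$ordination))
      out$ordination$coordinates
    write_results_bundle(bundle[!vapply(bundle, is.null, logical(1))], dir,
                         seed = config$seed,
                         config = unclass(config))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
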