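#' Run the full stratification pipeline
#'
#' Chains the pipeline stages in dependency order — synthetic cohort
#' generation, consensus clustering of solver submissions, discriminating
#' feature screen, and cluster assignment with cross-validation — writing
#' every artifact as plain CSV/JSON/DOT into a run directory together
#' with a JSON manifest (package version, seeds, parameters and MD5
#' hashes of every artifact).  An identical configuration reproduces
#' identical artifacts.  A stage requested without its prerequisite
#' artifacts raises an error naming what is missing.
#'
#' @param config a named list (or path to a YAML/JSON file) with optional
#'   components `seed`, `stages` (subset of `"synth"`, `"consensus"`,
#'   `"features"`, `"assign"`), `cohort` (arguments to [cohort_spec()]),
#'   `solvers` (arguments to [solver_spec()]), `consensus` (e.g. `k`,
#'   `n_perm`, `fdr_threshold`), `features` (e.g. `n_perm`), `assign`
#'   (e.g. `folds`, `fdr_cap`, `max_features`).
#' @param out_dir run directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  stages <- config$stages %||% c("synth", "consensus", "features", "assign")
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifact <- function(...) file.path(out_dir, ...)
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("stage ", shQuote(stage), " needs missing artifact ", path,
           "; run its upstream stage first")
    path
  }
  written <- character(0)
  note <- function(path) { written <<- unique(c(written, path)); path }

  if ("synth" %in% stages) {
    cs <- do.call(cohort_spec, config$cohort %||% list())
    cohort <- generate_cohort(cs, seed = child_seed(seed, 1L))
    ss <- do.call(solver_spec, config$solvers %||% list())
    subs <- generate_solver_submissions(cohort$labels, ss,
                                        seed = child_seed(seed, 2L))
    write_clinical_table(cohort$table, note(artifact("cohort.csv")))
    utils::write.csv(as.data.frame(cohort$dictionary),
                     note(artifact("dictionary.csv")), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = names(cohort$labels),
                                cluster = as.integer(cohort$labels)),
                     note(artifact("true_labels.csv")), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = names(cohort$slope_true),
                                slope = unname(cohort$slope_true)),
                     note(artifact("true_slopes.csv")), row.names = FALSE)
    utils::write.csv(cohort$survival_true,
                     note(artifact("true_survival.csv")), row.names = FALSE)
    write_submissions(subs, note(artifact("submissions.csv")))
  }

  if ("consensus" %in% stages) {
    subs <- read_submissions(need(artifact("submissions.csv"), "consensus"))
    cc_args <- config$consensus %||% list()
    fit <- consensus_clusters(
      subs, k = cc_args$k %||% 4L,
      n_perm = cc_args$n_perm %||% 100L,
      fdr_threshold = cc_args$fdr_threshold %||% 0.05,
      seed = child_seed(seed, 3L),
      n_restarts = cc_args$n_restarts %||% 10L)
    utils::write.csv(as.data.frame(fit$M), note(artifact("cocluster_M.csv")))
    utils::write.csv(as.data.frame(fit$pair_fdr),
                     note(artifact("pair_fdr.csv")), row.names = FALSE)
    write_pair_graph(fit$graph, note(artifact("pair_graph.dot")), "dot")
    write_pair_graph(fit$graph, note(artifact("pair_graph.graphml")),
                     "graphml")
    utils::write.csv(data.frame(subject_id = names(fit$labels),
                                cluster = as.integer(fit$labels),
                                core = as.logical(fit$core)),
                     note(artifact("consensus_labels.csv")),
                     row.names = FALSE)
  }

  if ("features" %in% stages) {
    tab <- read_clinical_table(need(artifact("cohort.csv"), "features"))
    dict <- read_feature_dictionary(need(artifact("dictionary.csv"),
                                         "features"))
    lab_df <- utils::read.csv(need(artifact("consensus_labels.csv"),
                                   "features"))
    g <- stats::setNames(as.integer(lab_df$cluster), lab_df$subject_id)
    fs <- summarize_features(tab, dict)
    fe_args <- config$features %||% list()
    fdr <- integrated_rank_fdr(fs, g = g,
                               n_perm = fe_args$n_perm %||% 100L,
                               seed = child_seed(seed, 4L))
    pw <- pairwise_ttest_fdr(fs, g, fdr)
    H <- heatmap_matrix(pw, clusters = sort(unique(unname(g))))
    utils::write.csv(as.data.frame(fs$C), note(artifact("summary_C.csv")))
    utils::write.csv(as.data.frame(fs$D), note(artifact("summary_D.csv")))
    utils::write.csv(fdr$table, note(artifact("feature_fdr.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pw), note(artifact("pairwise_fdr.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(H), note(artifact("heatmap.csv")))
  }

  if ("assign" %in% stages) {
    lab_df <- utils::read.csv(need(artifact("consensus_labels.csv"),
                                   "assign"))
    g <- stats::setNames(as.integer(lab_df$cluster), lab_df$subject_id)
    core <- stats::setNames(as.logical(lab_df$core), lab_df$subject_id)
    Cdf <- utils::read.csv(need(artifact("summary_C.csv"), "assign"),
                           row.names = 1L, check.names = FALSE)
    C <- as.matrix(Cdf)
    fdr_tab <- utils::read.csv(need(artifact("feature_fdr.csv"), "assign"))
    as_args <- config$assign %||% list()
    # rebuild the screen on the saved matrix so profiles come from code,
    # not from a stale table
    fdr <- integrated_rank_fdr(C, g = g,
                               n_perm = as_args$n_perm %||% 100L,
                               seed = child_seed(seed, 4L))
    prof <- build_profiles(C, g, fdr,
                           max_features = as_args$max_features %||% 20L,
                           fdr_cap = as_args$fdr_cap %||% 0.05)
    cv <- crossval_accuracy(C, g, folds = as_args$folds %||% 10L,
                            core_mask = if (isTRUE(as_args$core_only)) core,
                            n_perm = as_args$n_perm %||% 50L,
                            fdr_cap = as_args$fdr_cap %||% 0.05,
                            max_features = as_args$max_features %||% 20L,
                            seed = child_seed(seed, 5L))
    jsonlite::write_json(
      list(features = prof$features,
           center = as.list(prof$center), scale = as.list(prof$scale),
           centroids = as.data.frame(prof$centroids)),
      note(artifact("profiles.json")), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(accuracy = cv$accuracy, n_correct = cv$n_correct,
           n_assigned = cv$n_assigned),
      note(artifact("cv_accuracy.json")), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "alsconsensus",
    version = as.character(utils::packageVersion("alsconsensus")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, stages = stages, config = config,
    artifacts = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
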