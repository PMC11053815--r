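# End-to-end orchestration: protein + mutation list in, the per-cancer
# output file set (CD8/CD4 pair tables, filtered tables, Sequence.txt,
# manifest) out.

#' Pipeline run configuration
#'
#' @param cancer_name Name of the output folder (the cancer under study).
#' @param protein Path to a single-record FASTA, or a `protein_record`.
#' @param mutations Path to a mutation list file, or a list of
#'   `missense_mutation` objects.
#' @param out_dir Directory under which the `cancer_name` folder is created.
#' @param lengths_i,lengths_ii Window length sets (defaults `c(9, 10)` and
#'   `15`).
#' @param panel_i,panel_ii Allele panels (default built-in panels).
#' @param training Path to a training CSV (feature columns + `label`), a
#'   data.frame, or `NULL` to use the synthetic default table.
#' @param classifier_features,ranker_features Feature sets of the final
#'   models; defaults are the pipeline's production choices
#'   (antigenicity + hydropathicity + MHCflurry rank + rank ratio +
#'   stability for the classifier; rank + ratio + stability for the ranker).
#' @param registry Predictor registry; `NULL` builds the default mock-backed
#'   registry from `seed`.
#' @param filter_rules_i,filter_rules_ii Filter-rule overrides.
#' @param seed Integer seed for mocks, model fits and fold assignment.
#' @param safe_names Replace spaces in output file names with underscores.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cancer_name, protein, mutations, out_dir = ".",
                       lengths_i = c(9L, 10L), lengths_ii = 15L,
                       panel_i = default_allele_panel("I"),
                       panel_ii = default_allele_panel("II"),
                       training = NULL,
                       classifier_features = c("antigenicity",
                                               "hydropathicity",
                                               "mhcflurry_rank",
                                               "wt_mut_rank_ratio",
                                               "stability_halflife"),
                       ranker_features = c("mhcflurry_rank",
                                           "wt_mut_rank_ratio",
                                           "stability_halflife"),
                       registry = NULL,
                       filter_rules_i = default_filter_rules("I"),
                       filter_rules_ii = default_filter_rules("II"),
                       seed = 1L, safe_names = FALSE) {
  structure(list(cancer_name = cancer_name, protein = protein,
                 mutations = mutations, out_dir = out_dir,
                 lengths_i = lengths_i, lengths_ii = lengths_ii,
                 panel_i = panel_i, panel_ii = panel_ii, training = training,
                 classifier_features = classifier_features,
                 ranker_features = ranker_features, registry = registry,
                 filter_rules_i = filter_rules_i,
                 filter_rules_ii = filter_rules_ii,
                 seed = as.integer(seed), safe_names = safe_names),
            class = "run_config")
}

.load_training <- function(training, seed) {
  if (is.null(training)) {
    return(generate_training_dataset(synthetic_config(seed = seed)))
  }
  if (is.character(training)) {
    training <- utils::read.csv(training, stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(training)) {
    stop("training data needs a 'label' column", call. = FALSE)
  }
  training
}

#' Run the full epitope-selection pipeline
#'
#' Reads inputs, enumerates mutant epitope windows for both MHC classes,
#' expands them against the allele panels, populates features, trains (or
#' reuses) the classifier and ranker, classifies, scores and sorts the
#' class-I pairs, applies the exclusion filters to both classes, and writes
#' the output folder named after `cfg$cancer_name`:
#' `CD8 Epitopes.csv`, `CD8 Filtered Epitopes.csv`, `CD4 Epitopes.csv`,
#' `CD4 Filtered Epitopes.csv`, `Sequence.txt` (deduplicated mutant epitope
#' sequences, one per line), per-class filter audit CSVs and a
#' `manifest.yaml` recording configuration, seed and package version. A
#' wild-type mismatch in any mutation aborts before any file is written.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the output paths, the pair tables, the
#'   audits and the fitted models.
#' @export
run_pipeline <- function(cfg) {
  protein <- if (is.character(cfg$protein)) {
    read_protein_fasta(cfg$protein)
  } else cfg$protein
  mutations <- if (is.character(cfg$mutations)) {
    read_mutation_list(cfg$mutations)
  } else cfg$mutations
  for (m in mutations) apply_mutation(protein, m)  # validate all up front

  registry <- if (is.null(cfg$registry)) build_registry(cfg$seed) else
    cfg$registry

  training <- .load_training(cfg$training, cfg$seed)
  models <- train_final_models(
    training,
    model_spec("rf_classifier", cfg$classifier_features, seed = cfg$seed),
    model_spec("linear_regression", cfg$ranker_features, seed = cfg$seed)
  )

  cand_i <- enumerate_all_epitopes(protein, mutations, cfg$lengths_i, "I")
  cand_ii <- enumerate_all_epitopes(protein, mutations, cfg$lengths_ii, "II")
  pairs_i <- collect_features(make_ehla_pairs(cand_i, cfg$panel_i), registry)
  pairs_ii <- collect_features(make_ehla_pairs(cand_ii, cfg$panel_ii),
                               registry)
  pairs_i <- classify_and_rank(pairs_i, models)
  filt_i <- filter_ehla_i(pairs_i, cfg$filter_rules_i)
  filt_ii <- filter_ehla_ii(pairs_ii, cfg$filter_rules_ii)

  run_dir <- file.path(cfg$out_dir, cfg$cancer_name)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  fname <- function(x) if (cfg$safe_names) gsub(" ", "_", x, fixed = TRUE)
    else x
  paths <- c(
    cd8 = file.path(run_dir, fname("CD8 Epitopes.csv")),
    cd8_filtered = file.path(run_dir, fname("CD8 Filtered Epitopes.csv")),
    cd4 = file.path(run_dir, fname("CD4 Epitopes.csv")),
    cd4_filtered = file.path(run_dir, fname("CD4 Filtered Epitopes.csv")),
    sequence = file.path(run_dir, fname("Sequence.txt")),
    audit_cd8 = file.path(run_dir, fname("CD8 Filter Audit.csv")),
    audit_cd4 = file.path(run_dir, fname("CD4 Filter Audit.csv")),
    manifest = file.path(run_dir, "manifest.yaml")
  )
  utils::write.csv(pairs_i, paths["cd8"], row.names = FALSE)
  utils::write.csv(filt_i$kept, paths["cd8_filtered"], row.names = FALSE)
  utils::write.csv(pairs_ii, paths["cd4"], row.names = FALSE)
  utils::write.csv(filt_ii$kept, paths["cd4_filtered"], row.names = FALSE)
  writeLines(unique(c(pairs_i$mutant_sequence, pairs_ii$mutant_sequence)),
             paths["sequence"])
  utils::write.csv(filt_i$audit, paths["audit_cd8"], row.names = FALSE)
  utils::write.csv(filt_ii$audit, paths["audit_cd4"], row.names = FALSE)
  yaml::write_yaml(list(
    cancer_name = cfg$cancer_name,
    protein_id = protein$id,
    n_mutations = length(mutations),
    lengths_i = as.integer(cfg$lengths_i),
    lengths_ii = as.integer(cfg$lengths_ii),
    classifier_features = cfg$classifier_features,
    ranker_features = cfg$ranker_features,
    seed = cfg$seed,
    n_ehla_i = nrow(pairs_i), n_ehla_i_filtered = nrow(filt_i$kept),
    n_ehla_ii = nrow(pairs_ii), n_ehla_ii_filtered = nrow(filt_ii$kept),
    package_version = as.character(utils::packageVersion("epivax"))
  ), paths["manifest"])

  invisible(list(paths = paths, pairs_i = pairs_i,
                 pairs_i_filtered = filt_i$kept, audit_i = filt_i$audit,
                 pairs_ii = pairs_ii, pairs_ii_filtered = filt_ii$kept,
                 audit_ii = filt_ii$audit, models = models))
}
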