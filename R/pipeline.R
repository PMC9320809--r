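.hash_obj <- function(x) rlang::hash(x)

#' Assemble a pipeline run configuration
#'
#' Bundles paths, method choices and seeds for [run_all()]. Significance is
#' reported at `alpha` with no multiple-testing correction by default
#' (matching per-trait reporting conventions in this literature); set
#' `bh = TRUE` for Benjamini-Hochberg adjusted plasticity p-values.
#'
#' @param events Path to an event log readable by [read_event_log()].
#' @param chc Optional path to a CHC peak table for [normalize_chc()].
#' @param out_dir Output directory.
#' @param initiation_method,fitness,bootstrap,seed Method knobs passed
#'   through to the analysis stages.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param bh Apply Benjamini-Hochberg correction to plasticity p-values.
#' @param interval_s Grid interval for reading the event log.
#' @return Object of class `run_config`.
#' @export
run_config <- function(events, chc = NULL, out_dir = tempfile("courtship_run_"),
                       initiation_method = "consecutive3",
                       fitness = "inverse_latency", bootstrap = 2000,
                       seed = 1, alpha = 0.05, bh = FALSE, interval_s = 10) {
  if (!(alpha > 0 && alpha < 1)) {
    stop("config error: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (bootstrap < 100) {
    stop("config error: bootstrap replicates must be >= 100", call. = FALSE)
  }
  structure(list(
    events = events, chc = chc, out_dir = out_dir,
    initiation_method = initiation_method, fitness = fitness,
    bootstrap = bootstrap, seed = seed, alpha = alpha, bh = bh,
    interval_s = interval_s
  ), class = "run_config")
}

.budget_traits_present <- function(summaries) {
  traits <- paste0("budget_", active_states())
  keep <- vapply(traits, function(tr) {
    v <- summaries[[tr]]
    any(!is.na(v)) && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))
  traits[keep]
}

#' Run the full courtship-selection pipeline
#'
#' End-to-end analysis from an event log (plus optional CHC peak table) to
#' result tables: per-trial courtship summaries; an ART-ANOVA plasticity
#' table over the behavioral time budgets (male, female and interaction
#' effects per trait); per-male-strain transition-matrix homogeneity tests
#' between female contexts; selection gradients and binomial success
#' regressions per female strain (over budget traits and CHC compounds,
#' after random-forest variable reduction with the union of the two
#' contexts' selections); and a PCA of per-strain trait means in the first
#' female context. Tables are written as TSV/JSON into `out_dir` along with
#' a provenance manifest (package version, config and data hashes, output
#' hashes); identical config and data produce identical manifests.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summaries`, `plasticity`, `markov`,
#'   `selection`, `pca`, `selected_traits` and `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trials <- read_event_log(config$events, interval_s = config$interval_s)
  chc <- NULL
  if (!is.null(config$chc)) {
    if (!file.exists(config$chc)) {
      stop("configuration error: CHC file not found: ", config$chc, call. = FALSE)
    }
    chc <- normalize_chc(.read_delim_auto(config$chc))
  }
  summaries <- summarize_trials(trials, config$initiation_method, quiet = TRUE)

  # plasticity of behavioral time budgets, over courting trials of male
  # strains observed in every female context (the factorial needs full cells)
  courting <- summaries[!is.na(summaries$initiation_index), , drop = FALSE]
  ctx_per_strain <- tapply(courting$female_strain, courting$male_strain,
                           function(x) length(unique(x)))
  full <- names(ctx_per_strain)[ctx_per_strain == length(unique(summaries$female_strain))]
  courting <- courting[courting$male_strain %in% full, , drop = FALSE]
  budget_traits <- .budget_traits_present(courting)
  plast_rows <- lapply(budget_traits, function(tr) {
    res <- tryCatch(art_anova(courting, response = tr), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(trait = sub("^budget_", "", tr),
               effect = res$effect, F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  })
  plast_rows <- Filter(Negate(is.null), plast_rows)
  if (length(plast_rows) == 0L) {
    stop("degenerate statistics: no budget trait supports the factorial model",
         call. = FALSE)
  }
  plasticity <- do.call(rbind, plast_rows)
  if (config$bh) {
    plasticity$p_adj <- stats::p.adjust(plasticity$p, method = "BH")
  }
  plasticity$significant <- plasticity[[if (config$bh) "p_adj" else "p"]] < config$alpha

  # behavioral-sequence homogeneity per male strain across female contexts
  females <- sort(unique(summaries$female_strain))
  markov_rows <- lapply(sort(unique(summaries$male_strain)), function(ms) {
    groups <- lapply(females, function(fs) {
      grp <- Filter(function(tr) tr$male_strain == ms && tr$female_strain == fs,
                    trials)
      if (length(grp) == 0L) return(NULL)
      count_transitions(grp)
    })
    groups <- Filter(Negate(is.null), groups)
    if (length(groups) < 2L) return(NULL)
    ht <- tryCatch(homogeneity_test(groups), error = function(e) NULL)
    if (is.null(ht)) return(NULL)
    data.frame(male_strain = ms, statistic = ht$statistic, df = ht$df,
               p = ht$p.value, significant = ht$p.value < config$alpha,
               stringsAsFactors = FALSE)
  })
  markov <- do.call(rbind, Filter(Negate(is.null), markov_rows))

  # selection gradients per female context after variable reduction
  trait_tables <- lapply(females, function(fs) {
    build_trait_table(summaries, fs, chc = chc)
  })
  names(trait_tables) <- females
  candidate_traits <- lapply(trait_tables, function(tt) {
    setdiff(names(tt), c("male_strain", "female_strain", "successes", "trials",
                         "mean_latency_s", "n_courting"))
  })
  selected <- unique(unlist(lapply(seq_along(females), function(i) {
    tt <- trait_tables[[i]]
    ok <- tt$successes > 0 & !is.na(tt$mean_latency_s)
    traits <- candidate_traits[[i]]
    x <- tt[ok, traits, drop = FALSE]
    usable <- traits[vapply(traits, function(tr) {
      !any(is.na(x[[tr]])) && stats::sd(x[[tr]]) > 0
    }, logical(1))]
    if (length(usable) < 2L || sum(ok) < 4L) return(usable)
    w <- relative_fitness(tt$mean_latency_s[ok], config$fitness)
    variable_select(x[usable], w, seed = config$seed)
  })))
  if (length(selected) == 0L) selected <- unique(unlist(candidate_traits))
  selection <- do.call(rbind, lapply(females, function(fs) {
    tt <- trait_tables[[fs]]
    usable <- selected[vapply(selected, function(tr) {
      v <- tt[[tr]][tt$successes > 0]
      !any(is.na(v)) && stats::sd(v) > 0
    }, logical(1))]
    selection_analysis(tt, usable, fitness = config$fitness,
                       bootstrap = config$bootstrap, seed = config$seed)
  }))

  # PCA of per-strain trait means in the first (Z-like) context
  tt1 <- trait_tables[[1]]
  pca_cols <- candidate_traits[[1]][vapply(candidate_traits[[1]], function(tr) {
    !any(is.na(tt1[[tr]])) && stats::sd(tt1[[tr]]) > 0
  }, logical(1))]
  pca <- if (length(pca_cols) >= 2L && nrow(tt1) >= 3L) {
    res <- pca_traits(as.matrix(tt1[pca_cols]))
    rownames(res$scores) <- tt1$male_strain
    res
  } else {
    NULL
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    summaries = file.path(config$out_dir, "summaries.tsv"),
    plasticity = file.path(config$out_dir, "table1.tsv"),
    markov = file.path(config$out_dir, "markov.tsv"),
    selection = file.path(config$out_dir, "table2.tsv")
  )
  write_results(summaries, paths$summaries, "tsv")
  write_results(plasticity, paths$plasticity, "tsv")
  if (!is.null(markov)) write_results(markov, paths$markov, "tsv")
  write_results(selection, paths$selection, "tsv")
  if (!is.null(pca)) {
    jsonlite::write_json(
      list(var_explained = pca$var_explained,
           scores = as.data.frame(pca$scores),
           loadings = as.data.frame(pca$loadings)),
      file.path(config$out_dir, "pca.json"), digits = NA, dataframe = "columns"
    )
  }
  manifest <- list(
    package = "courtshipSelect",
    version = as.character(utils::packageVersion("courtshipSelect")),
    seed = config$seed,
    config_hash = .hash_obj(config[setdiff(names(config), "out_dir")]),
    data_hash = .hash_obj(list(trials = trials, chc = chc)),
    output_hash = .hash_obj(list(summaries = summaries, plasticity = plasticity,
                                 markov = markov, selection = selection,
                                 pca = pca))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(summaries = summaries, plasticity = plasticity,
                 markov = markov, selection = selection, pca = pca,
                 selected_traits = selected, manifest = manifest))
}
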