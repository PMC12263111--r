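# End-to-end pipeline: assemble annotation sources (from files or from a
# simulation), run every metric stage that its inputs allow, and render a
# combined comparison report. Stages are independent: a source with only
# HOGs still gets HOG metrics, one with only pairs still gets ortholog
# proportions, and a failed stage is recorded without stopping the rest.

#' Pipeline run configuration
#'
#' @param sources list of annotation-source specifications. Each is a
#'   list with `label` and any of: `fasta` (named character vector,
#'   species -> FASTA path), `gff` (named vector of GFF3 paths),
#'   `dialect` (GFF3 dialect), `splice` (named vector of .splice paths),
#'   `pairs` (pairwise-ortholog TSV path), `orthoxml` (OrthoXML path),
#'   `profile` (phyletic-profile TSV path).
#' @param species_tree Newick path/string, or an [ape::phylo] tree.
#' @param simulate optional `SimulationConfig`; when given, two in-memory
#'   sources `clean` and `perturbed` are generated and appended.
#' @param benchmark list of [benchmark_config()] arguments.
#' @param seed global seed (also used by the benchmark).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(sources = list(), species_tree = NULL,
                       simulate = NULL,
                       benchmark = list(n_trials = 200L,
                                        min_species = 10L),
                       seed = 1L) {
  labels <- vapply(sources, function(s) s$label, "")
  if (anyDuplicated(labels)) stop_data("duplicate source labels")
  for (s in sources) {
    paths <- c(s$fasta, s$gff, s$splice, s$pairs, s$orthoxml, s$profile)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_data("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(sources = sources, species_tree = species_tree,
                 simulate = simulate, benchmark = benchmark,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Demo configuration: simulation plus all metric stages
#'
#' A small self-contained run (12 species, 60 families, moderate
#' perturbation) that exercises every stage in well under a minute; used
#' as the quickstart.
#'
#' @param seed global seed.
#' @return a `RunConfig`.
#' @export
demo_config <- function(seed = 1L) {
  run_config(
    simulate = simulation_config(
      n_species = 12L, n_families = 60L,
      birth_rate = 0.05, death_rate = 0.05,
      substitution_rate = 0.3,
      miss_prob = 0.05, frag_prob = 0.15, spurious_rate = 0.2,
      boundary_jitter = 10L, seed = seed),
    benchmark = list(n_trials = 150L, min_species = 7L),
    seed = seed)
}

# Load the file-backed inputs of one source specification.
load_source <- function(spec) {
  src <- list(label = spec$label, proteomes = NULL, annotations = NULL,
              pairs = NULL, hogs = NULL)
  if (!is.null(spec$fasta)) {
    src$proteomes <- lapply(names(spec$fasta), function(sp) {
      p <- parse_fasta(spec$fasta[[sp]], species = sp,
                       label = spec$label)
      splice <- if (!is.null(spec$splice) && sp %in% names(spec$splice))
        parse_splice(spec$splice[[sp]], proteome = p) else NULL
      select_canonical_longest(p, splice)
    })
    names(src$proteomes) <- names(spec$fasta)
  }
  if (!is.null(spec$gff)) {
    src$annotations <- lapply(names(spec$gff), function(sp)
      parse_gff3(spec$gff[[sp]], dialect = spec$dialect %||% "generic",
                 species = sp, label = spec$label))
    names(src$annotations) <- names(spec$gff)
  }
  if (!is.null(spec$pairs)) src$pairs <- parse_pairwise(spec$pairs)
  if (!is.null(spec$orthoxml)) src$hogs <- parse_orthoxml(spec$orthoxml)
  else if (!is.null(spec$profile)) src$hogs <- parse_profile_tsv(spec$profile)
  src
}

# Metric block for one assembled source.
source_metrics <- function(src, tree, bench_cfg) {
  out <- list(label = src$label, stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e)
                      list(ok = FALSE, value = conditionMessage(e)))
    out$stages[[name]] <<- if (res$ok) "ok" else
      paste("failed:", res$value)
    if (res$ok) res$value else NULL
  }
  if (!is.null(src$proteomes)) {
    out$gene_counts <- run_stage("gene_counts", {
      data.frame(
        species = names(src$proteomes),
        n_genes = vapply(src$proteomes,
                         function(p) sum(p$canonical), 0L),
        stringsAsFactors = FALSE)
    })
  }
  if (!is.null(src$proteomes) && !is.null(src$pairs)) {
    out$proportions <- run_stage("ortholog_proportions",
                                 ortholog_proportions(src$proteomes,
                                                      src$pairs))
    out$length_split <- run_stage("length_split", {
      det <- attr(out$proportions, "details")
      splits <- lapply(names(src$proteomes), function(sp)
        split_by_orthology(src$proteomes[[sp]], det[[sp]]))
      with_l <- unlist(lapply(splits,
                              function(s) s$with_orthologs$lengths))
      sing_l <- unlist(lapply(splits, function(s) s$singletons$lengths))
      data.frame(group = c("with_orthologs", "singletons"),
                 n = c(length(with_l), length(sing_l)),
                 median_length = c(median_length(with_l),
                                   if (length(sing_l)) median_length(sing_l)
                                   else NA_real_),
                 stringsAsFactors = FALSE)
    })
  }
  if (!is.null(src$proteomes)) {
    out$lengths <- run_stage("length_stats", {
      samples <- lapply(names(src$proteomes), function(sp)
        length_sample(sp, protein_lengths(src$proteomes[[sp]],
                                          canonical_only = TRUE)))
      km <- if (length(samples) >= 2L) ks_matrix(samples) else NULL
      list(medians = data.frame(
             species = names(src$proteomes),
             median_length = vapply(samples, median_length, 0),
             stringsAsFactors = FALSE),
           avg_ks = if (is.null(km)) NA_real_ else km$average)
    })
    if (!is.null(out$proportions) && nrow(out$proportions) >= 3L &&
        stats::sd(out$proportions$proportion) > 0 &&
        stats::sd(out$lengths$medians$median_length) > 0) {
      out$length_vs_proportion_r <- run_stage("length_correlation",
        pearson_r(out$lengths$medians$median_length,
                  out$proportions$proportion))
    }
  }
  if (!is.null(src$hogs)) {
    out$hog_metrics <- run_stage("hog_metrics", {
      hs <- hog_sizes(src$hogs)
      comp <- tryCatch(hog_completeness_all(src$hogs, tree),
                       error = function(e) NULL)
      strict <- count_pattern(src$hogs,
                              phyletic_pattern(others = 1L,
                                               species = src$hogs$species))
      list(n_roothogs = hs$n_roothogs,
           share_two_member = if (hs$n_roothogs)
             mean(hs$sizes == 2L) else NA_real_,
           mean_completeness = if (is.null(comp)) NA_real_
                               else mean(comp),
           strict_single_copy = strict)
    })
  }
  if (!is.null(src$proteomes) && !is.null(src$pairs) &&
      !is.null(tree)) {
    out$benchmark <- run_stage("benchmark",
      run_benchmark(src$proteomes, src$pairs, tree, bench_cfg))
  }
  out
}

#' Run the full comparison pipeline
#'
#' Executes, per source and as inputs allow: gene counts, ortholog
#' proportions, ortholog/singleton length splits, length statistics, HOG
#' metrics and the species-tree discordance benchmark; plus gene-model
#' agreement across all sources sharing a species. Identical config and
#' seed yield an identical report.
#'
#' @param config a `RunConfig`.
#' @return an object of class `ComparisonReport`.
#' @export
run_pipeline <- function(config) {
  tree <- config$species_tree
  if (is.character(tree)) tree <- parse_newick(tree)
  sources <- lapply(config$sources, load_source)
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    if (is.null(tree)) tree <- config$simulate$species_tree
    sources <- c(sources, list(
      list(label = "clean", proteomes = sim$clean$proteomes,
           annotations = sim$clean$annotations,
           pairs = sim$true_pairs, hogs = sim$true_hogs),
      list(label = "perturbed", proteomes = sim$perturbed$proteomes,
           annotations = sim$perturbed$annotations,
           pairs = sim$observed_pairs, hogs = sim$observed_hogs)))
  }
  bench_cfg <- do.call(benchmark_config,
                       c(config$benchmark, list(seed = config$seed)))
  metrics <- lapply(sources, source_metrics, tree = tree,
                    bench_cfg = bench_cfg)
  names(metrics) <- vapply(sources, function(s) s$label, "")

  ann_sets <- unlist(lapply(sources, function(s) s$annotations),
                     recursive = FALSE)
  agreement <- if (length(ann_sets) >= 2L)
    tryCatch(pairwise_agreement(unname(ann_sets)),
             error = function(e) NULL)
  else NULL

  cfg_file <- tempfile()
  writeLines(deparse(config[c("benchmark", "seed")]), cfg_file)
  structure(list(
    provenance = list(package = "orthoqc",
                      version = as.character(utils::packageVersion("orthoqc")),
                      seed = config$seed,
                      config_hash = unname(tools::md5sum(cfg_file))),
    sources = metrics,
    agreement = agreement),
    class = "ComparisonReport")
}

round_df <- function(df, digits = 9L) {
  for (i in seq_along(df))
    if (is.numeric(df[[i]])) df[[i]] <- round(df[[i]], digits)
  df
}

#' Render a comparison report to TSV tables and a JSON summary
#'
#' Writes `summary.json` plus one TSV per table (`proportions.tsv`,
#' `lengths.tsv`, `length_split.tsv`, `hogs.tsv`, `benchmark.tsv`,
#' `agreement.tsv`). Missing stages are rendered as explicit nulls in the
#' JSON and absent TSVs. Numbers are written with fixed precision, so a
#' rerun at the same seed is byte-identical.
#'
#' @param report a `ComparisonReport`.
#' @param dir output directory (created if needed).
#' @param format `"tsv+json"` (default), `"json"` or `"tsv"`.
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, format = "tsv+json") {
  if (!format %in% c("tsv+json", "json", "tsv"))
    stop_data("unknown format '", format, "'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit_tsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(round_df(df), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <<- c(written, path)
  }
  tables <- list()
  for (lab in names(report$sources)) {
    m <- report$sources[[lab]]
    add <- function(tbl, df) {
      if (is.null(df)) return()
      df <- cbind(source = lab, df)
      tables[[tbl]] <<- rbind(tables[[tbl]], df)
    }
    add("proportions.tsv", m$proportions)
    add("lengths.tsv", m$lengths$medians)
    add("length_split.tsv", m$length_split)
    if (!is.null(m$hog_metrics))
      add("hogs.tsv", as.data.frame(m$hog_metrics))
    if (!is.null(m$benchmark))
      add("benchmark.tsv",
          data.frame(n_trials = m$benchmark$n_trials,
                     n_success = m$benchmark$n_success,
                     mean_scaled_rf = m$benchmark$mean_scaled_rf))
  }
  if (!is.null(report$agreement))
    tables[["agreement.tsv"]] <- report$agreement$per_species
  if (format %in% c("tsv+json", "tsv"))
    for (nm in names(tables)) emit_tsv(tables[[nm]], nm)
  if (format %in% c("tsv+json", "json")) {
    summary <- list(provenance = report$provenance,
                    sources = lapply(report$sources, function(m) {
      list(stages = m$stages,
           median_proportion = if (!is.null(m$proportions))
             median(m$proportions$proportion) else NULL,
           avg_ks = if (!is.null(m$lengths)) m$lengths$avg_ks else NULL,
           length_vs_proportion_r = m$length_vs_proportion_r,
           hog_metrics = m$hog_metrics,
           benchmark = if (!is.null(m$benchmark))
             list(n_trials = m$benchmark$n_trials,
                  n_success = m$benchmark$n_success,
                  mean_scaled_rf = m$benchmark$mean_scaled_rf)
           else NULL)
    }),
                    agreement_medians = if (!is.null(report$agreement))
                      report$agreement$medians else NULL)
    path <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = 9,
                         null = "null", pretty = TRUE)
    written <- c(written, path)
  }
  invisible(written)
}
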