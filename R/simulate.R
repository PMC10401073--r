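# Seeded simulators for the three kinds of input the pipeline consumes.
# All are pure functions of their configs: the same config (including
# seed) reproduces byte-identical output, and per-sample draws use
# sub-seeds derived from the master seed so adding a timepoint or sample
# does not perturb the others.

#' Screen simulation configuration
#'
#' Defaults mirror the screened library: 191 genes of interest, 50 control
#' genes and 10 essential genes with 5 sgRNAs each, plus 75 cutting and 75
#' non-cutting control guides (1,405 guides), sampled on days 5, 8, 11,
#' 16 and 20 post infection.
#'
#' The growth model is exponential: guide abundance at day `d` is
#' `initial * 2^((growth_rate - effect) * (d - reference day) / doubling_time)`,
#' with `growth_rate` doublings per day for neutral guides and a
#' per-(gene, cell line) fitness penalty `effect` (in doublings/day) for
#' knockouts that impair growth. Initial abundances are log-normal.
#' Sequencing is multinomial over guide abundances at a fixed per-sample
#' total (`n_guides * reads_per_guide_mean` reads), so totals are exact;
#' set `overdispersion` to a finite Dirichlet-multinomial concentration
#' for overdispersed counts.
#'
#' @param n_genes_of_interest,n_control_genes,n_essential Gene counts.
#' @param guides_per_gene Guides per targeted gene.
#' @param n_cutting_controls,n_noncutting_controls Control guide counts.
#' @param days Sampling days; must include `reference_day`.
#' @param reference_day First sampled day (abundance reference). Default 5.
#' @param reads_per_guide_mean Mean sequencing reads per guide. Default 1000.
#' @param initial_abundance_dispersion Log-normal sigma of initial guide
#'   abundances. Default 0.5.
#' @param growth_rate Neutral growth, doublings/day. Default 1.
#' @param doubling_time Days per doubling at unit growth rate. Default 1.
#' @param essential_effect Penalty applied to `essential` genes in every
#'   cell line. Default 1 (growth fully arrested).
#' @param dropout_effect Penalty for planted selective dropouts. Default 2
#'   (abundance halves per day at the default growth rate).
#' @param fitness_effects Data frame `gene`, `cell_line`, `effect` of
#'   planted per-line penalties, or `NULL`.
#' @param cell_lines Two cell-line identifiers.
#' @param overdispersion `Inf` (default) for exact multinomial sampling;
#'   a finite positive concentration for Dirichlet-multinomial.
#' @param seed Master seed; fixes all randomness.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes_of_interest = 191L,
                              n_control_genes = 50L,
                              n_essential = 10L,
                              guides_per_gene = 5L,
                              n_cutting_controls = 75L,
                              n_noncutting_controls = 75L,
                              days = c(5L, 8L, 11L, 16L, 20L),
                              reference_day = 5L,
                              reads_per_guide_mean = 1000,
                              initial_abundance_dispersion = 0.5,
                              growth_rate = 1,
                              doubling_time = 1,
                              essential_effect = 1,
                              dropout_effect = 2,
                              fitness_effects = NULL,
                              cell_lines = c("lineA", "lineB"),
                              overdispersion = Inf,
                              seed = 1L) {
  for (n in c(n_genes_of_interest, n_control_genes, n_essential,
              guides_per_gene, n_cutting_controls, n_noncutting_controls))
    if (!is_count(n)) stop_input("library composition counts must be non-negative integers")
  if (!reference_day %in% days) stop_input("days must include the reference day")
  if (reads_per_guide_mean <= 0) stop_input("reads_per_guide_mean must be positive")
  if (!is.null(fitness_effects)) {
    miss <- setdiff(c("gene", "cell_line", "effect"), names(fitness_effects))
    if (length(miss))
      stop_input("fitness_effects missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!(is.infinite(overdispersion) || overdispersion > 0))
    stop_input("overdispersion must be positive or Inf")
  structure(as.list(environment()), class = "screen_sim_config")
}

#' @rdname screen_sim_config
#' @param cfg A `screen_sim_config`.
#' @return `sim_library(cfg)`: the [screen_library()] implied by the
#'   configured composition, with genes `GOI###`, `CTG###`, `ESS###` and
#'   control guides `CUT###`/`NC###`.
#' @export
sim_library <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  gene_block <- function(prefix, n, category) {
    if (n == 0L) return(NULL)
    genes <- sprintf("%s%03d", prefix, seq_len(n))
    data.frame(guide_id = paste0(rep(genes, each = cfg$guides_per_gene), "_g",
                                 seq_len(cfg$guides_per_gene)),
               gene = rep(genes, each = cfg$guides_per_gene),
               category = category, stringsAsFactors = FALSE)
  }
  ctrl_block <- function(prefix, n, category) {
    if (n == 0L) return(NULL)
    data.frame(guide_id = sprintf("%s%03d", prefix, seq_len(n)),
               gene = NA_character_, category = category,
               stringsAsFactors = FALSE)
  }
  screen_library(rbind(
    gene_block("GOI", cfg$n_genes_of_interest, "gene_of_interest"),
    gene_block("CTG", cfg$n_control_genes, "control_gene"),
    gene_block("ESS", cfg$n_essential, "essential"),
    ctrl_block("CUT", cfg$n_cutting_controls, "cutting_control"),
    ctrl_block("NC", cfg$n_noncutting_controls, "noncutting_control")),
    guides_per_gene = cfg$guides_per_gene)
}

#' Simulate a two-line pooled CRISPR dropout screen
#'
#' See [screen_sim_config()] for the generative model. Essential genes
#' receive `essential_effect` in both cell lines; planted
#' `fitness_effects` add per-line penalties on top.
#'
#' @param cfg A [screen_sim_config()].
#' @return List with `counts_a`, `counts_b` ([count_matrix()] per cell
#'   line) and `truth` (library, planted per-guide effects, config echo).
#' @examples
#' sim <- simulate_screen(screen_sim_config(seed = 7))
#' colSums(sim$counts_a$counts)  # exact multinomial totals
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  lib <- sim_library(cfg)
  n_guides <- nrow(lib)
  effects <- matrix(0, n_guides, 2,
                    dimnames = list(lib$guide_id, cfg$cell_lines))
  effects[lib$category == "essential", ] <- cfg$essential_effect
  if (!is.null(cfg$fitness_effects)) {
    fe <- cfg$fitness_effects
    unknown <- setdiff(fe$gene, lib$gene)
    if (length(unknown))
      stop_input("fitness effect references unknown gene(s): ",
                 paste(unknown, collapse = ", "))
    bad_line <- setdiff(fe$cell_line, cfg$cell_lines)
    if (length(bad_line))
      stop_input("fitness effect references unknown cell line(s): ",
                 paste(bad_line, collapse = ", "))
    for (i in seq_len(nrow(fe))) {
      rows <- which(!is.na(lib$gene) & lib$gene == fe$gene[i])
      effects[rows, fe$cell_line[i]] <-
        effects[rows, fe$cell_line[i]] + fe$effect[i]
    }
  }
  init <- with_seed(derive_seed(cfg$seed, "init"),
                    rlnorm(n_guides, 0, cfg$initial_abundance_dispersion))
  names(init) <- lib$guide_id
  total_reads <- round(n_guides * cfg$reads_per_guide_mean)

  one_line <- function(line) {
    counts <- sapply(cfg$days, function(d) {
      abund <- init * 2^((cfg$growth_rate - effects[, line]) *
                           (d - cfg$reference_day) / cfg$doubling_time)
      prob <- abund / sum(abund)
      with_seed(derive_seed(cfg$seed, line, d), {
        if (is.finite(cfg$overdispersion))
          prob <- rgamma(n_guides, shape = cfg$overdispersion * prob) |>
            (\(g) g / sum(g))()
        rmultinom(1, total_reads, prob)[, 1]
      })
    })
    dimnames(counts) <- list(lib$guide_id, paste0("D", cfg$days))
    count_matrix(counts, lib, line)
  }
  counts <- lapply(cfg$cell_lines, one_line)
  list(counts_a = counts[[1]], counts_b = counts[[2]],
       truth = list(library = lib, effects = effects,
                    initial_abundance = init, total_reads = total_reads,
                    config = cfg))
}

#' Simulate binomial heteroplasmy pileups
#'
#' Alt-allele read counts are Binomial(depth, fraction); the remaining
#' reads carry the reference base.
#'
#' @param true_heteroplasmies Data frame `position`, `ref`, `alt`,
#'   `fraction` of true variant fractions.
#' @param depth Reads per site.
#' @param n_replicates Independent pileup sets to draw.
#' @param seed Master seed.
#' @return List with `pileups` (list of length `n_replicates`, each a list
#'   of [pileup_column()]s) and `truth` (the config echo).
#' @export
simulate_pileups <- function(true_heteroplasmies, depth = 2000L,
                             n_replicates = 1L, seed = 1L) {
  th <- true_heteroplasmies
  miss <- setdiff(c("position", "ref", "alt", "fraction"), names(th))
  if (length(miss))
    stop_input("true_heteroplasmies missing column(s): ", paste(miss, collapse = ", "))
  check_fraction(th$fraction, "fraction")
  if (!is_count(depth) || depth <= 0) stop_input("depth must be a positive integer")
  pileups <- lapply(seq_len(n_replicates), function(r)
    lapply(seq_len(nrow(th)), function(i) {
      n_alt <- with_seed(derive_seed(seed, "pileup", r, i),
                         rbinom(1, depth, th$fraction[i]))
      counts <- setNames(c(depth - n_alt, n_alt), c(th$ref[i], th$alt[i]))
      # ref and alt keys may coincide only for indel keys; SNVs differ
      pileup_column(th$position[i], th$ref[i], counts)
    }))
  list(pileups = pileups,
       truth = list(true_heteroplasmies = th, depth = depth,
                    n_replicates = n_replicates, seed = seed))
}

#' Simulate a per-base coverage profile with an optional planted deletion
#'
#' Depth is Poisson(`baseline_depth`) per base; inside the deletion
#' interval (which may wrap the origin) the rate is scaled by
#' `1 - del_fraction`.
#'
#' @param baseline_depth Mean reads per base; must be positive.
#' @param deletion `NULL`, or a list/vector with `start`, `end` (1-based
#'   inclusive, `start > end` wraps) and `del_fraction` in \[0, 1\].
#' @param genome_length Genome length.
#' @param sample_id Sample identifier.
#' @param seed Master seed.
#' @return List with `coverage` (a [coverage_profile()]) and `truth`.
#' @examples
#' sim <- simulate_coverage(1000, deletion = list(start = 3000, end = 6709,
#'                                                del_fraction = 0.6), seed = 1)
#' @export
simulate_coverage <- function(baseline_depth, deletion = NULL,
                              genome_length = MT_GENOME_LENGTH,
                              sample_id = "sim", seed = 1L) {
  if (!is.numeric(baseline_depth) || baseline_depth <= 0)
    stop_input("baseline_depth must be positive")
  rate <- rep(baseline_depth, genome_length)
  if (!is.null(deletion)) {
    deletion <- as.list(deletion)
    check_fraction(deletion$del_fraction, "del_fraction")
    pos <- interval_positions(as.integer(deletion$start),
                              as.integer(deletion$end), genome_length)
    rate[pos] <- baseline_depth * (1 - deletion$del_fraction)
  }
  depth <- with_seed(derive_seed(seed, "coverage", sample_id),
                     rpois(genome_length, rate))
  list(coverage = coverage_profile(sample_id, depth, genome_length),
       truth = list(baseline_depth = baseline_depth, deletion = deletion,
                    genome_length = genome_length, seed = seed))
}
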