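#' Specification for a synthetic gene-set collection
#'
#' The fixture generator emulates the situation every tool in this package is
#' built for: a pile of noisy, independently derived experimental gene lists
#' that partially agree on a common biological signal. A chosen group of
#' *signal* genes joins each set independently with probability `p_signal`
#' (consilient hits recurring across experiments), and each set is padded
#' with uniformly drawn *background* genes (study-specific noise). The
#' planted truth is returned with the collection so recovery can be scored.
#'
#' The defaults describe a mid-sized curated collection: 20 sets over a
#' 230-gene universe with 30 signal genes appearing in 90% of sets and 10
#' background genes per set.
#'
#' @param n_sets Number of gene sets.
#' @param universe_size Total genes available (signal + background pool).
#' @param species Character vector of species tags; sets are assigned species
#'   cyclically, and with more than one species gene identifiers are
#'   species-qualified (`"<species>_<gene>"`) so homology mapping is
#'   meaningful.
#' @param n_signal_genes Number of planted signal genes.
#' @param p_signal Probability a signal gene joins any given set.
#' @param background_per_set Background genes drawn uniformly (without
#'   replacement) into each set.
#' @param disjoint_background Partition the background pool across sets so
#'   background genes never recur (guaranteeing empty pairwise intersections
#'   when `p_signal = 0`).
#' @param seed Integer seed governing all randomness.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_sets = 20L, universe_size = 230L,
                         species = "mouse", n_signal_genes = 30L,
                         p_signal = 0.9, background_per_set = 10L,
                         disjoint_background = FALSE, seed = 1L) {
  if (n_signal_genes > universe_size) {
    stop_data("n_signal_genes must not exceed universe_size")
  }
  if (p_signal < 0 || p_signal > 1) stop_data("p_signal must lie in [0, 1]")
  if (disjoint_background &&
      n_sets * background_per_set > universe_size - n_signal_genes) {
    stop_data("background pool too small for disjoint backgrounds")
  }
  structure(
    list(
      n_sets = as.integer(n_sets), universe_size = as.integer(universe_size),
      species = as.character(species),
      n_signal_genes = as.integer(n_signal_genes), p_signal = p_signal,
      background_per_set = as.integer(background_per_set),
      disjoint_background = isTRUE(disjoint_background),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

fixture_genes <- function(spec) {
  sprintf("g%04d", seq_len(spec$universe_size))
}

qualify <- function(species, gene, multi) {
  if (length(gene) == 0L || !multi) return(gene)
  paste(species, gene, sep = "_")
}

#' Generate a synthetic collection with planted signal
#'
#' @param spec A [fixture_spec()].
#' @return List with `collection` (a [gene_set_collection()]) and `truth`, a
#'   tibble (`gene_id`, `species`, `base_gene`, `is_signal`) recording the
#'   planted role of every universe gene in every species' identifier space.
#'   Identical seeds yield identical output.
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- fixture_genes(spec)
  multi <- length(spec$species) > 1L
  withr::with_seed(spec$seed, {
    signal <- sample(genes, spec$n_signal_genes)
    background_pool <- setdiff(genes, signal)
    if (spec$disjoint_background) {
      chunks <- split(
        background_pool[seq_len(spec$n_sets * spec$background_per_set)],
        rep(seq_len(spec$n_sets), each = spec$background_per_set)
      )
    }
    sets <- vector("list", spec$n_sets)
    for (i in seq_len(spec$n_sets)) {
      sp <- spec$species[[(i - 1L) %% length(spec$species) + 1L]]
      in_set <- signal[stats::runif(length(signal)) < spec$p_signal]
      bg <- if (spec$disjoint_background) chunks[[i]] else {
        sample(background_pool, spec$background_per_set)
      }
      members <- c(in_set, bg)
      if (length(members) == 0L) members <- sample(background_pool, 1L)
      sets[[i]] <- gene_set(
        sprintf("set%03d", i), qualify(sp, sw_sort(members), multi),
        name = sprintf("synthetic set %d", i),
        abbreviation = sprintf("S%d", i),
        description = sprintf("synthetic fixture (seed %d)", spec$seed),
        species = sp, tier = "V"
      )
    }
  })
  truth <- bind_rows(lapply(spec$species, function(sp) {
    tibble(
      gene_id = qualify(sp, genes, multi),
      species = sp, base_gene = genes,
      is_signal = genes %in% signal
    )
  }))
  list(collection = gene_set_collection(sets), truth = truth)
}

#' Generate a synthetic homology cluster index
#'
#' One cluster per universe gene; the first (reference) species' ortholog is
#' always present and each further species' ortholog is included with
#' probability `p_present`, so `p_present = 1` gives clusters spanning all
#' species and `p_present = 0` leaves non-reference genes as singletons at
#' harmonization time.
#'
#' @param spec A [fixture_spec()] with at least two species.
#' @param p_present Inclusion probability for non-reference orthologs.
#' @return A [cluster_index()] with `universe_size` clusters.
#' @export
generate_homology <- function(spec, p_present = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (length(spec$species) < 2L) {
    stop_data("generate_homology needs at least two species")
  }
  genes <- fixture_genes(spec)
  rows <- withr::with_seed(spec$seed + 1L, {
    bind_rows(lapply(seq_along(spec$species), function(si) {
      sp <- spec$species[[si]]
      present <- if (si == 1L) rep(TRUE, length(genes)) else {
        stats::runif(length(genes)) < p_present
      }
      if (!any(present)) {
        return(tibble(cluster_id = character(), species = character(),
                      gene_id = character()))
      }
      tibble(
        cluster_id = paste0("c_", genes[present]),
        species = sp,
        gene_id = qualify(sp, genes[present], TRUE)
      )
    }))
  })
  cluster_index(rows)
}

#' Mirror a collection into another species
#'
#' Produces the cross-species twin of a collection by replacing each gene
#' with its ortholog in the target species, via a homology index. Genes
#' whose cluster has no ortholog in the target species are dropped with a
#' warning. Useful for exercising harmonization: with complete homology the
#' mirrored sets harmonize to exactly the originals' cluster sets.
#'
#' @param collection A [gene_set_collection()].
#' @param index A [cluster_index()].
#' @param species Target species tag.
#' @param suffix Appended to each mirrored `set_id` to keep ids unique.
#' @return A `gene_set_collection` in the target species' identifier space.
#' @export
mirror_collection <- function(collection, index, species, suffix = "_m") {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(index, "cluster_index"))
  tgt <- index$mapping[index$mapping$species == species, ]
  sets <- lapply(collection$sets, function(gs) {
    cl <- cluster_of(index, gs$species, gs$members)
    mirrored <- tgt$gene_id[match(cl, tgt$cluster_id)]
    lost <- is.na(mirrored)
    if (any(lost)) {
      warn(sprintf("%s: %d gene(s) without %s ortholog dropped",
                   gs$set_id, sum(lost), species))
    }
    mirrored <- unique(mirrored[!lost])
    if (length(mirrored) == 0L) return(NULL)
    gene_set(
      paste0(gs$set_id, suffix), mirrored,
      name = paste(gs$name, "(mirrored)"),
      abbreviation = paste0(gs$abbreviation, suffix),
      description = gs$description,
      species = species, tier = gs$tier
    )
  })
  gene_set_collection(Filter(Negate(is.null), sets))
}

#' Generate synthetic gene-publication and publication-term tables
#'
#' Random bipartite literature associations for exercising
#' [build_term_genesets()]: each gene appears in a Poisson-distributed number
#' of publications and each publication is tagged with a Poisson-distributed
#' number of terms (at least one each), all drawn uniformly.
#'
#' @param n_genes,n_pubs,n_terms Table dimensions.
#' @param mean_pubs_per_gene,mean_terms_per_pub Poisson means for association
#'   counts.
#' @param seed Integer seed.
#' @return List of tibbles `gene_pub` (`gene_id`, `pub_id`) and `pub_term`
#'   (`pub_id`, `term`), deduplicated.
#' @export
generate_association_tables <- function(n_genes = 50L, n_pubs = 30L,
                                        n_terms = 5L,
                                        mean_pubs_per_gene = 3,
                                        mean_terms_per_pub = 2,
                                        seed = 1L) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  pubs <- sprintf("p%04d", seq_len(n_pubs))
  terms <- sprintf("T%02d", seq_len(n_terms))
  withr::with_seed(seed, {
    gene_pub <- bind_rows(lapply(genes, function(g) {
      k <- max(1L, stats::rpois(1L, mean_pubs_per_gene))
      tibble(gene_id = g, pub_id = sample(pubs, min(k, n_pubs)))
    }))
    pub_term <- bind_rows(lapply(pubs, function(p) {
      k <- max(1L, stats::rpois(1L, mean_terms_per_pub))
      tibble(pub_id = p, term = sample(terms, min(k, n_terms)))
    }))
  })
  list(gene_pub = distinct(gene_pub), pub_term = distinct(pub_term))
}
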