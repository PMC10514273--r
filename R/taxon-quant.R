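#' Taxon quantification: counts, CPM, genus aggregation and filtering
#'
#' Converts accepted read assignments into filtered genus-level relative
#' read abundance (RRA) and frequency-of-occurrence (FOO) tables. The
#' pipeline order is fixed: tabulate at species rank, aggregate to genus
#' (with an explicit split list for congeners analyzed separately), remove
#' bait, apply the per-sample prevalence threshold, apply the local-flora
#' allow-list, then derive RRA/FOO. Tables are plain samples x taxa
#' matrices with a "rank" attribute.
#'
#' @name taxon_quant
NULL

#' Tabulate accepted assignments into a species-rank count table
#'
#' @param assignments data.frame with sample_id, accession (one row per
#'   accepted read); a `query_id` column is carried along but unused.
#' @param taxonomy data.frame mapping accession to genus and species.
#' @return samples x species integer matrix (rank attribute "species").
#' @export
tabulate_assignments <- function(assignments, taxonomy) {
  unknown <- setdiff(unique(assignments$accession), taxonomy$accession)
  if (length(unknown) > 0)
    stopf("accessions missing from taxonomy: %s",
          paste(unknown, collapse = ", "))
  sp <- taxonomy$species[match(assignments$accession, taxonomy$accession)]
  tab <- table(assignments$sample_id, sp)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  attr(m, "rank") <- "species"
  m
}

#' Normalize a count table to counts per million mapped reads
#'
#' @param tab samples x taxa count matrix.
#' @return matrix whose rows sum to 1e6; zero-total samples are dropped
#'   with a warning.
#' @export
cpm_normalize <- function(tab) {
  rs <- rowSums(tab)
  if (any(rs == 0)) {
    warnf("dropping %d zero-count sample(s): %s", sum(rs == 0),
          paste(rownames(tab)[rs == 0], collapse = ", "))
    tab <- tab[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  out <- tab * 1e6 / rs
  attr(out, "rank") <- attr(tab, "rank")
  attr(out, "scale") <- "cpm"
  out
}

#' Aggregate a species-rank table to genus rank, with split exceptions
#'
#' Species in `split_species` keep their own column labeled by binomial
#' (e.g. the two Croton species analyzed separately); the genus column of a
#' split genus holds only its non-split congeners.
#'
#' @param tab species-rank table (columns are binomials "Genus species").
#' @param split_species binomials kept separate.
#' @return genus-rank matrix.
#' @export
aggregate_genus <- function(tab, split_species = character(0)) {
  species <- colnames(tab)
  unknown <- setdiff(split_species, species)
  if (length(unknown) > 0)
    stopf("split species not present: %s", paste(unknown, collapse = ", "))
  target <- ifelse(species %in% split_species, species,
                   vapply(strsplit(species, " ", fixed = TRUE), `[`, "", 1L))
  groups <- unique(target)
  out <- vapply(groups, function(g)
    rowSums(tab[, target == g, drop = FALSE]), numeric(nrow(tab)))
  out <- matrix(out, nrow = nrow(tab),
                dimnames = list(rownames(tab), groups))
  attr(out, "rank") <- "genus"
  out
}

#' Remove bait taxa and summarize their prevalence
#'
#' @param tab genus-rank table.
#' @param bait bait genus labels (millet defaults).
#' @return list(table, summary = list(foo = fraction of samples containing
#'   bait, read_share = bait share of all reads)).
#' @export
remove_bait <- function(tab, bait = "Panicum") {
  present <- intersect(bait, colnames(tab))
  if (length(present) == 0) {
    return(list(table = tab, summary = list(foo = 0, read_share = 0)))
  }
  bait_counts <- rowSums(tab[, present, drop = FALSE])
  summary <- list(foo = mean(bait_counts > 0),
                  read_share = sum(bait_counts) / sum(tab))
  out <- tab[, setdiff(colnames(tab), present), drop = FALSE]
  attr(out, "rank") <- attr(tab, "rank")
  list(table = out, summary = summary)
}

#' Drop taxa never reaching a within-sample proportion threshold
#'
#' A taxon is retained iff its within-sample proportion is >= `min_frac` in
#' at least one sample; proportions use the current (post-bait-removal) row
#' totals.
#'
#' @param tab count table.
#' @param min_frac per-sample proportion threshold in \[0, 1).
#' @return filtered table.
#' @export
prevalence_threshold <- function(tab, min_frac = 0.01) {
  if (min_frac < 0 || min_frac >= 1) stopf("min_frac must be in [0, 1)")
  rs <- rowSums(tab)
  prop <- tab / ifelse(rs == 0, 1, rs)
  keep <- apply(prop, 2L, function(col) any(col >= min_frac))
  out <- tab[, keep, drop = FALSE]
  attr(out, "rank") <- attr(tab, "rank")
  out
}

#' Retain only taxa on a local-flora allow-list
#'
#' @param tab count table.
#' @param allow_list taxon labels with local botanical records.
#' @return list(table, removed = data.frame(taxon, total_rra) reporting
#'   dropped taxa and their share of reads).
#' @export
flora_filter <- function(tab, allow_list) {
  if (length(allow_list) == 0)
    stopf("empty allow-list would silently drop every taxon; refusing")
  drop <- setdiff(colnames(tab), allow_list)
  removed <- data.frame(
    taxon = drop,
    total_rra = if (length(drop)) colSums(tab[, drop, drop = FALSE]) / sum(tab)
                else numeric(0),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- tab[, setdiff(colnames(tab), drop), drop = FALSE]
  attr(out, "rank") <- attr(tab, "rank")
  list(table = out, removed = removed)
}

#' Relative read abundance and frequency of occurrence
#'
#' `to_rra` renormalizes each sample to proportions (rows sum to 1; all-zero
#' rows stay zero and are flagged in the "empty_samples" attribute);
#' `to_foo` gives each taxon's fraction of samples with a nonzero count.
#'
#' @param tab count table.
#' @return proportion matrix / named FOO vector.
#' @export
to_rra <- function(tab) {
  rs <- rowSums(tab)
  out <- tab / ifelse(rs == 0, 1, rs)
  attr(out, "rank") <- attr(tab, "rank")
  attr(out, "scale") <- "rra"
  attr(out, "empty_samples") <- rownames(tab)[rs == 0]
  out
}

#' @rdname to_rra
#' @export
to_foo <- function(tab) {
  colMeans(tab > 0)
}

#' Evaluate mock-community recovery
#'
#' @param observed observed RRA proportions for the mock sample (named).
#' @param truth known mixing proportions (named, sums to 1).
#' @param min_frac threshold above which an unexpected taxon counts as a
#'   false detection.
#' @return list(table = per-taxon observed vs expected, correlation =
#'   Pearson r, max_abs_dev, false_detections, missed).
#' @export
mock_recovery <- function(observed, truth, min_frac = 0.01) {
  taxa <- union(names(observed), names(truth))
  obs <- stats::setNames(rep(0, length(taxa)), taxa)
  exp <- obs
  obs[names(observed)] <- observed
  exp[names(truth)] <- truth
  tabd <- data.frame(taxon = taxa, observed = unname(obs),
                     expected = unname(exp), stringsAsFactors = FALSE)
  false_det <- taxa[exp == 0 & obs >= min_frac]
  missed <- taxa[exp > 0 & obs == 0]
  list(table = tabd,
       correlation = if (stats::sd(obs) > 0 && stats::sd(exp) > 0)
         stats::cor(obs, exp) else NA_real_,
       max_abs_dev = max(abs(obs - exp)),
       false_detections = false_det,
       missed = missed)
}

#' Run the fixed quantification chain
#'
#' tabulate -> aggregate to genus -> remove bait -> prevalence threshold ->
#' flora filter -> RRA/FOO. Returns every intermediate so the order is
#' auditable.
#'
#' @param assignments accepted read assignments (sample_id, accession).
#' @param taxonomy accession -> (genus, species) map.
#' @param allow_list local-flora allow-list.
#' @param split_species binomials kept separate at genus rank.
#' @param bait bait genus labels.
#' @param min_frac prevalence threshold.
#' @return list with species_counts, genus_counts, bait_summary, filtered
#'   counts, rra, foo, removed_taxa.
#' @export
quantify_pipeline <- function(assignments, taxonomy, allow_list,
                              split_species = c("Croton californicus",
                                                "Croton setiger"),
                              bait = "Panicum", min_frac = 0.01) {
  sp_tab <- tabulate_assignments(assignments, taxonomy)
  split_species <- intersect(split_species, colnames(sp_tab))
  gen_tab <- aggregate_genus(sp_tab, split_species)
  rb <- remove_bait(gen_tab, bait)
  thr <- prevalence_threshold(rb$table, min_frac)
  ff <- flora_filter(thr, allow_list)
  list(species_counts = sp_tab,
       genus_counts = gen_tab,
       bait_summary = rb$summary,
       counts = ff$table,
       removed_taxa = ff$removed,
       rra = to_rra(ff$table),
       foo = to_foo(ff$table))
}
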