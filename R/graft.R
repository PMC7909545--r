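#' Graft missing taxa onto a phylogeny next to congeners
#'
#' Completes a megatree for a community analysis: every matrix taxon absent
#' from the tree is attached to the terminal branch of a randomly chosen
#' congener (uniform among tips sharing the genus), or — for subspecies —
#' to their parent species' tip.  The target's terminal branch of length
#' l is split at `fraction * l` below the tip and the new tip attached
#' there with an equal pendant, so the grafted pair stays ultrametric
#' relative to each other and no original tip changes depth.
#'
#' Grafts are applied sequentially in input order; a freshly grafted tip is
#' immediately a legal congener target for later grafts.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param taxa A data frame with columns `taxon`, optional `genus` (default:
#'   token before the first underscore or space of `taxon`) and optional
#'   `parent_species` (non-`NA`/non-empty marks a subspecies graft).
#' @param seed Integer seed controlling congener choice.
#' @param fraction Where on the terminal branch to attach, as a fraction of
#'   its length measured from the tip (default 0.5, the midpoint).
#' @return The augmented `phylo` tree.
#' @examples
#' tr <- ape::read.tree(text = "((A_x:1,A_y:1):1,B_z:2);")
#' out <- graft_missing_taxa(tr, tibble::tibble(taxon = "A_w"), seed = 1)
#' ape::Ntip(out)
#' @export
graft_missing_taxa <- function(tree, taxa, seed, fraction = 0.5) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(taxa))
  if (!"taxon" %in% names(taxa))
    stop("`taxa` needs a `taxon` column", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  taxa <- tibble::as_tibble(taxa)
  if (!"genus" %in% names(taxa) || all(is.na(taxa$genus)))
    taxa$genus <- genus_of(taxa$taxon)
  taxa$genus[is.na(taxa$genus)] <- genus_of(taxa$taxon[is.na(taxa$genus)])
  if (!"parent_species" %in% names(taxa))
    taxa$parent_species <- NA_character_
  taxa$parent_species[taxa$parent_species %in% ""] <- NA_character_

  if (anyDuplicated(c(tree$tip.label, taxa$taxon)))
    stop("duplicate tip labels after grafting: ",
         paste(unique(c(tree$tip.label, taxa$taxon)[
           duplicated(c(tree$tip.label, taxa$taxon))]), collapse = ", "),
         call. = FALSE)

  # orphan check against the final tip set (earlier grafts count)
  all_tips <- c(tree$tip.label, taxa$taxon)
  ok <- vapply(seq_len(nrow(taxa)), function(i) {
    if (!is.na(taxa$parent_species[i]))
      return(taxa$parent_species[i] %in% all_tips)
    any(genus_of(setdiff(all_tips, taxa$taxon[i])) == taxa$genus[i])
  }, logical(1))
  if (!all(ok))
    stop("taxa with no congener and no parent species in the tree: ",
         paste(taxa$taxon[!ok], collapse = ", "), call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(taxa))) {
    target <- if (!is.na(taxa$parent_species[i])) {
      taxa$parent_species[i]
    } else {
      cands <- tree$tip.label[genus_of(tree$tip.label) == taxa$genus[i]]
      if (!length(cands))
        stop("no congener available for ", taxa$taxon[i], call. = FALSE)
      cands[sample.int(length(cands), 1L)]
    }
    wi <- match(target, tree$tip.label)
    if (is.na(wi)) stop("graft target not in tree: ", target, call. = FALSE)
    len <- tree$edge.length[tree$edge[, 2] == wi]
    tree <- phytools::bind.tip(tree, taxa$taxon[i],
                               edge.length = fraction * len,
                               where = wi, position = fraction * len)
  }
  tree
}

#' Extract the genus token from taxon labels
#'
#' The genus is the token before the first underscore or space.
#'
#' @param labels Character vector of taxon labels.
#' @return Character vector of genus names.
#' @export
genus_of <- function(labels) sub("[_ ].*$", "", labels)
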