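#' Diploid multilocus genotype table
#'
#' Container for diploid microsatellite calls. Alleles are stored as two
#' integer matrices (one per gene copy) with individuals in rows and loci in
#' columns; allele codes are repeat-size units (positive integers) and a
#' missing genotype is `NA` in both copies.
#'
#' @param individual_id character vector of unique individual identifiers.
#' @param site_id character vector, one site per individual.
#' @param a1,a2 integer matrices (`n_ind x n_loci`) holding the two allele
#'   copies of each genotype; both entries of a genotype must be `NA` or both
#'   present.
#' @param locus_names character vector of locus names (columns of `a1`/`a2`).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individual_id, site_id, a1, a2, locus_names) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual_id)
  if (length(site_id) != n) stop("site_id must match individual_id in length")
  if (anyDuplicated(individual_id)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  }
  if (nrow(a1) != n || nrow(a2) != n) stop("allele matrices must have one row per individual")
  if (ncol(a1) != length(locus_names) || ncol(a2) != length(locus_names))
    stop("allele matrices must have one column per locus")
  if (any(xor(is.na(a1), is.na(a2)))) {
    bad <- which(rowSums(xor(is.na(a1), is.na(a2))) > 0)[1]
    stop("half-missing genotype for individual ", individual_id[bad],
         "; both alleles of a genotype must be missing or both present")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(individual_id, locus_names)
  structure(
    list(individual_id = as.character(individual_id),
         site_id = as.character(site_id),
         a1 = a1, a2 = a2,
         locus_names = as.character(locus_names)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individual_id), "individuals,",
      length(x$locus_names), "loci,",
      length(unique(x$site_id)), "sites\n")
  invisible(x)
}

n_individuals <- function(tab) length(tab$individual_id)

#' Subset a genotype table
#'
#' @param tab a `genotype_table`.
#' @param individuals logical/integer/character index of individuals to keep.
#' @param loci optional index of loci to keep.
#' @return A `genotype_table` restricted to the selection.
#' @export
gt_subset <- function(tab, individuals = NULL, loci = NULL) {
  ii <- seq_along(tab$individual_id)
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals)) match(individuals, tab$individual_id) else ii[individuals]
    if (anyNA(ii)) stop("unknown individual in subset")
  }
  ll <- seq_along(tab$locus_names)
  if (!is.null(loci)) {
    ll <- if (is.character(loci)) match(loci, tab$locus_names) else ll[loci]
    if (anyNA(ll)) stop("unknown locus in subset")
  }
  genotype_table(tab$individual_id[ii], tab$site_id[ii],
                 tab$a1[ii, ll, drop = FALSE], tab$a2[ii, ll, drop = FALSE],
                 tab$locus_names[ll])
}

#' Restrict a genotype table to a set of sites
#' @param tab a `genotype_table`.
#' @param sites character vector of site ids to keep.
#' @return A `genotype_table` containing only individuals from `sites`.
#' @export
gt_sites <- function(tab, sites) {
  miss <- setdiff(sites, tab$site_id)
  if (length(miss)) stop("no individuals for site(s): ", paste(miss, collapse = ", "))
  gt_subset(tab, tab$site_id %in% sites)
}

#' Concatenate genotype tables sharing a locus set
#' @param ... `genotype_table` objects with identical `locus_names`.
#' @return The row-bound `genotype_table`.
#' @export
gt_bind <- function(...) {
  tabs <- list(...)
  loci <- tabs[[1]]$locus_names
  for (t in tabs) if (!identical(t$locus_names, loci)) stop("locus sets differ")
  genotype_table(
    unlist(lapply(tabs, `[[`, "individual_id")),
    unlist(lapply(tabs, `[[`, "site_id")),
    do.call(rbind, lapply(tabs, `[[`, "a1")),
    do.call(rbind, lapply(tabs, `[[`, "a2")),
    loci)
}
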