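#' Aligned mtDNA haplotype set
#'
#' @param individual_id character vector of unique ids.
#' @param sequence character vector of aligned DNA strings over `{A,C,G,T,N,-}`;
#'   all the same length.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(individual_id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(individual_id) != length(sequence)) stop("id/sequence length mismatch")
  if (anyDuplicated(individual_id))
    stop("duplicate sequence id: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  w <- unique(nchar(sequence))
  if (length(w) > 1) {
    off <- individual_id[nchar(sequence) != w[1]]
    stop("sequences are not all the same aligned length; offending record(s): ",
         paste(off, collapse = ", "))
  }
  bad <- grepl("[^ACGTN-]", sequence)
  if (any(bad)) stop("non-DNA characters in sequence for: ",
                     paste(individual_id[bad], collapse = ", "))
  structure(list(individual_id = as.character(individual_id),
                 sequence = sequence,
                 length = if (length(w)) w else 0L),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$individual_id), "sequences of length", x$length, "\n")
  invisible(x)
}

#' Read an aligned FASTA file into a haplotype set
#'
#' Record ids are taken from the header up to the first whitespace and bases
#' are upper-cased. All records must share the alignment length.
#'
#' @param path path to a FASTA file.
#' @return A [haplotype_set()].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  haplotype_set(ids, as.character(seqs))
}

#' Write a haplotype set as FASTA
#' @param haps a `haplotype_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(haps, path) {
  writeLines(paste0(">", haps$individual_id, "\n", haps$sequence), path)
  invisible(path)
}

## ---- GENEPOP ---------------------------------------------------------------

#' Read a GENEPOP file
#'
#' Accepts the 2- or 3-digit diploid dialect with `POP`-delimited blocks.
#' `00`/`000` allele codes are parsed as missing. Site ids are recovered from
#' individual names of the form `site:individual` (the convention used by
#' [write_genepop()]); blocks without that convention are named `pop1`,
#' `pop2`, ...
#'
#' @param path path to a GENEPOP file.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) stop("GENEPOP parse error: file too short")
  # line 1 is the title; locus names follow, one per line or comma-separated
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("GENEPOP parse error: no POP line found")
  locus_lines <- lines[2:(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GENEPOP parse error: empty locus header at line 2")
  if (anyDuplicated(loci)) stop("GENEPOP parse error: duplicate locus name in header")
  L <- length(loci)

  ids <- character(); sites <- character()
  a1 <- list(); a2 <- list()
  blocks <- c(pop_idx, length(lines) + 1L)
  for (b in seq_along(pop_idx)) {
    rows <- lines[seq(blocks[b] + 1L, blocks[b + 1L] - 1L)]
    if (blocks[b] + 1L > blocks[b + 1L] - 1L) rows <- character()
    for (r in rows) {
      parts <- strsplit(r, ",")[[1]]
      if (length(parts) < 2)
        stop("GENEPOP parse error: no comma in individual row '", trimws(r), "'")
      nm <- trimws(parts[1])
      gfields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(gfields) != L)
        stop("ragged genotype row for individual '", nm, "': ",
             length(gfields), " loci, expected ", L)
      w <- unique(nchar(gfields))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop("GENEPOP parse error: genotype fields for '", nm,
             "' are not uniform 4- or 6-character diploid codes")
      d <- w / 2L
      x1 <- as.integer(substr(gfields, 1L, d))
      x2 <- as.integer(substr(gfields, d + 1L, w))
      if (anyNA(x1) || anyNA(x2))
        stop("GENEPOP parse error: non-numeric genotype for '", nm, "'")
      x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
      # a genotype is all-or-nothing missing
      half <- xor(is.na(x1), is.na(x2))
      if (any(half)) { x1[half] <- NA_integer_; x2[half] <- NA_integer_ }
      if (grepl(":", nm, fixed = TRUE)) {
        sites <- c(sites, sub(":.*$", "", nm))
        ids <- c(ids, sub("^[^:]*:", "", nm))
      } else {
        sites <- c(sites, paste0("pop", b))
        ids <- c(ids, nm)
      }
      a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
    }
  }
  genotype_table(ids, sites, do.call(rbind, a1), do.call(rbind, a2), loci)
}

#' Write a genotype table as GENEPOP
#'
#' Sites are written as `POP` blocks ordered as in `site_order` (or the
#' metadata order when a site table is given), individuals lexically within a
#' block, with 3-digit allele coding and `000000` for missing. Individual
#' names are written as `site:individual` so that [read_genepop()] round-trips
#' the site assignment.
#'
#' @param tab a [genotype_table()].
#' @param sites optional: a site metadata data frame (see
#'   [read_site_metadata()]) or a character vector giving the site order.
#' @param path output path.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(tab, sites = NULL, path, title = "oxbowflow export") {
  if (any(tab$a1 > 999L, na.rm = TRUE) || any(tab$a2 > 999L, na.rm = TRUE))
    stop("allele codes > 999 cannot be written in the 3-digit GENEPOP dialect")
  site_order <- if (is.null(sites)) sort(unique(tab$site_id))
    else if (is.data.frame(sites)) sites$site_id else as.character(sites)
  site_order <- intersect(site_order, tab$site_id)
  extra <- setdiff(tab$site_id, site_order)
  site_order <- c(site_order, sort(extra))
  out <- c(title, tab$locus_names)
  code <- function(x) { y <- sprintf("%03d", ifelse(is.na(x), 0L, x)); y }
  for (s in site_order) {
    out <- c(out, "POP")
    ii <- which(tab$site_id == s)
    ii <- ii[order(tab$individual_id[ii])]
    for (i in ii) {
      g <- paste0(code(tab$a1[i, ]), code(tab$a2[i, ]), collapse = " ")
      out <- c(out, paste0(s, ":", tab$individual_id[i], " ,  ", g))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a genotype table in STRUCTURE format
#'
#' One row per individual: id, integer site index, then two columns per locus
#' with `-9` for missing, tab-delimited, with a locus-name header row.
#'
#' @param tab a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(tab, path) {
  site_idx <- as.integer(factor(tab$site_id, levels = unique(tab$site_id)))
  L <- length(tab$locus_names)
  g <- matrix(-9L, nrow = n_individuals(tab), ncol = 2L * L)
  g[, seq(1L, 2L * L, by = 2L)] <- ifelse(is.na(tab$a1), -9L, tab$a1)
  g[, seq(2L, 2L * L, by = 2L)] <- ifelse(is.na(tab$a2), -9L, tab$a2)
  header <- paste(c("", "", rep(tab$locus_names, each = 2L)), collapse = "\t")
  rows <- apply(cbind(tab$individual_id, site_idx, g), 1L, paste, collapse = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

## ---- site metadata ---------------------------------------------------------

.roles <- c("cis", "trans", "control", "pure")
.lats <- c("north", "central", "south", "none")
.banks <- c("west", "east")

#' Read and validate a site metadata table
#'
#' Tab-delimited UTF-8 with columns `site_id`, `role`
#' (`cis`/`trans`/`control`/`pure`), `latitude_group`
#' (`north`/`central`/`south`/`none`), `bank_current`, `bank_historical`
#' (`west`/`east`), and optional `oxbow_id` and `parent_id`. A row with a
#' non-empty `parent_id` is a member sampling location pooled into its parent
#' site at load time.
#'
#' Validated invariants: `role == "pure"` iff `latitude_group == "none"`; cis
#' sites have `bank_current != bank_historical`; all other roles have equal
#' banks; member rows must agree with their parent on role, banks and
#' latitude.
#'
#' @param path path to the metadata file, or a data frame with the same
#'   columns.
#' @return A validated data frame of site metadata.
#' @export
read_site_metadata <- function(path) {
  md <- if (is.data.frame(path)) path
    else utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site_id", "role", "latitude_group", "bank_current", "bank_historical")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!"oxbow_id" %in% names(md)) md$oxbow_id <- NA_character_
  if (!"parent_id" %in% names(md)) md$parent_id <- NA_character_
  md$parent_id[!is.na(md$parent_id) & md$parent_id == ""] <- NA_character_
  if (anyDuplicated(md$site_id)) stop("duplicate site_id in metadata")
  if (!all(md$role %in% .roles)) stop("unknown role; must be one of ", paste(.roles, collapse = "/"))
  if (!all(md$latitude_group %in% .lats)) stop("unknown latitude_group")
  if (!all(md$bank_current %in% .banks) || !all(md$bank_historical %in% .banks))
    stop("banks must be west/east")
  if (any((md$role == "pure") != (md$latitude_group == "none")))
    stop("metadata error: role 'pure' must pair with latitude_group 'none' and vice versa")
  cis_bad <- md$role == "cis" & md$bank_current == md$bank_historical
  if (any(cis_bad))
    stop("metadata error: cis site(s) with equal current and historical banks: ",
         paste(md$site_id[cis_bad], collapse = ", "))
  other_bad <- md$role != "cis" & md$bank_current != md$bank_historical
  if (any(other_bad))
    stop("metadata error: non-cis site(s) with differing banks: ",
         paste(md$site_id[other_bad], collapse = ", "))
  orphan <- !is.na(md$parent_id) & !(md$parent_id %in% md$site_id)
  if (any(orphan)) stop("member location(s) reference unknown parent: ",
                        paste(md$site_id[orphan], collapse = ", "))
  for (i in which(!is.na(md$parent_id))) {
    p <- md[md$site_id == md$parent_id[i], ]
    same <- all(md[i, c("role", "latitude_group", "bank_current", "bank_historical")] ==
                p[, c("role", "latitude_group", "bank_current", "bank_historical")])
    if (!same) stop("member location ", md$site_id[i], " disagrees with parent ", p$site_id)
  }
  md
}

#' Write site metadata as tab-delimited text
#' @param md site metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## ---- study assembly --------------------------------------------------------

#' Assemble a study dataset from files
#'
#' Reads genotypes (GENEPOP), sequences (FASTA) and site metadata, cross
#' references them, applies site pooling (member sampling locations are
#' relabelled to their parent site), and validates the result. Individuals
#' without a sequence are retained with the haplotype marked absent;
#' individuals referencing a site absent from the metadata are an error.
#'
#' @param genotype_path GENEPOP file path (or a `genotype_table`).
#' @param fasta_path FASTA path (or a `haplotype_set`), or `NULL` for none.
#' @param metadata_path metadata path (or a metadata data frame).
#' @param pool logical: pool member locations into parent sites (default TRUE).
#' @return A `study_dataset`: list with `genotypes`, `haplotypes`, `sites`.
#' @export
load_study <- function(genotype_path, fasta_path, metadata_path, pool = TRUE) {
  tab <- if (inherits(genotype_path, "genotype_table")) genotype_path else read_genepop(genotype_path)
  haps <- if (is.null(fasta_path)) haplotype_set(character(), character())
    else if (inherits(fasta_path, "haplotype_set")) fasta_path else read_fasta(fasta_path)
  md <- read_site_metadata(metadata_path)
  unknown <- setdiff(unique(tab$site_id), md$site_id)
  if (length(unknown))
    stop("individual(s) reference site(s) missing from metadata: ",
         paste(unknown, collapse = ", "))
  n_in <- n_individuals(tab)
  if (pool && any(!is.na(md$parent_id))) {
    map <- ifelse(is.na(md$parent_id), md$site_id, md$parent_id)
    names(map) <- md$site_id
    tab$site_id <- unname(map[tab$site_id])
    md <- md[is.na(md$parent_id), ]  # member rows fold into their parents
  }
  extra_h <- setdiff(haps$individual_id, tab$individual_id)
  if (length(extra_h))
    warning("sequence(s) without genotyped individual dropped: ",
            paste(extra_h, collapse = ", "))
  keep <- haps$individual_id %in% tab$individual_id
  haps <- haplotype_set(haps$individual_id[keep], haps$sequence[keep])
  study <- structure(list(genotypes = tab, haplotypes = haps, sites = md),
                     class = "study_dataset")
  stopifnot(n_individuals(study$genotypes) == n_in)  # never silently drop
  validate_study(study)
  # heavily missing loci are flagged, not excluded
  for (s in unique(tab$site_id)) {
    ii <- tab$site_id == s
    fr <- colMeans(is.na(tab$a1[ii, , drop = FALSE]))
    if (any(fr > 0.5))
      warning("locus(es) >50% missing at site ", s, ": ",
              paste(tab$locus_names[fr > 0.5], collapse = ", "))
  }
  study
}

validate_study <- function(study) {
  stopifnot(inherits(study$genotypes, "genotype_table"),
            inherits(study$haplotypes, "haplotype_set"))
  unknown <- setdiff(unique(study$genotypes$site_id), study$sites$site_id)
  if (length(unknown)) stop("site(s) without metadata: ", paste(unknown, collapse = ", "))
  cnt <- table(study$genotypes$site_id)
  if (any(cnt < 1)) stop("site with no individuals")
  invisible(study)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", n_individuals(x$genotypes), "individuals,",
      length(x$genotypes$locus_names), "msat loci,",
      length(x$haplotypes$individual_id), "mtDNA sequences,",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Write a study dataset to disk
#'
#' Emits the GENEPOP, FASTA and metadata files that [load_study()] reads back.
#'
#' @param study a `study_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(prefix, ".genepop.txt"))
  fa <- file.path(dir, paste0(prefix, ".cytb.fasta"))
  mdp <- file.path(dir, paste0(prefix, ".sites.tsv"))
  write_genepop(study$genotypes, study$sites, gp)
  write_fasta(study$haplotypes, fa)
  write_site_metadata(study$sites, mdp)
  invisible(c(genotypes = gp, fasta = fa, metadata = mdp))
}

#' Per-reaction genotyping error rate
#'
#' Mismatched re-genotyped reactions divided by total re-genotyped reactions.
#'
#' @param n_mismatch number of mismatched genotypes.
#' @param n_reactions total re-genotyped reactions; must be positive.
#' @return The error rate per reaction.
#' @export
genotyping_error_rate <- function(n_mismatch, n_reactions) {
  if (n_reactions <= 0) stop("error rate undefined: n_reactions must be positive")
  if (n_mismatch < 0 || n_mismatch > n_reactions)
    stop("n_mismatch must lie in [0, n_reactions]")
  n_mismatch / n_reactions
}
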