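#' Family membership filtering, naming and protein statistics
#'
#' Candidate family members come from protein homology searches against known
#' family proteins; membership requires a hit passing all three thresholds
#' (E-value, percent identity, query coverage) simultaneously, plus a
#' complete conserved domain in the required evidence sources. Confirmed
#' genes are named by chromosomal order.
#'
#' @name family_identification
NULL

#' Filter homology hits to candidate family members
#'
#' A query passes if ANY single hit satisfies all three thresholds at once.
#' All boundaries are inclusive.
#'
#' @param hits data.table from [read_hit_table()].
#' @param evalue_max maximum E-value (default 1e-5).
#' @param identity_min minimum percent identity (default 60).
#' @param coverage_min minimum query coverage fraction (default 0.5).
#' @return sorted character vector of unique passing query ids.
#' @export
filter_candidates <- function(hits, evalue_max = 1e-5, identity_min = 60,
                              coverage_min = 0.5) {
  stopifnot(evalue_max > 0, identity_min >= 0, coverage_min >= 0)
  hits <- as.data.table(hits)
  if (!nrow(hits)) return(character())
  if (any(hits$identity < 0 | hits$identity > 100)) stop("identity outside [0,100]")
  if (any(hits$evalue < 0)) stop("negative e-value")
  pass <- hits[evalue <= evalue_max & identity >= identity_min & coverage >= coverage_min]
  sort(unique(pass$query_id))
}

#' Confirm candidates by conserved-domain evidence
#'
#' A candidate is confirmed iff, in every required source, it has at least
#' one evidence row with `status == "complete"` and E-value at or below the
#' cutoff. Truncated or absent domains eliminate the candidate; candidates
#' with no evidence rows at all are treated as domain-absent.
#'
#' @param candidates character vector of candidate ids.
#' @param evidence data.table: `protein_id`, `domain_id`, `source`
#'   (hmm/smart/pfam/cdd), `evalue`, `status` (complete/truncated/absent).
#' @param require_sources sources that must each confirm (default `"hmm"`).
#' @param evalue_max domain E-value cutoff (default 1e-5).
#' @return list: `confirmed` (character vector), `rejected` (data.table with
#'   `protein_id`, `reason`).
#' @export
confirm_domain <- function(candidates, evidence, require_sources = "hmm",
                           evalue_max = 1e-5) {
  evidence <- as.data.table(evidence)
  ok_src <- c("hmm", "smart", "pfam", "cdd")
  if (nrow(evidence) && !all(evidence$source %in% ok_src)) {
    stop("unknown evidence source: ",
         setdiff(unique(evidence$source), ok_src)[1])
  }
  confirmed <- character()
  rejected <- list()
  for (id in candidates) {
    rows <- evidence[protein_id == id]
    if (!nrow(rows)) {
      rejected[[id]] <- "no domain evidence (treated as absent)"
      next
    }
    bad <- NULL
    for (src in require_sources) {
      srows <- rows[source == src]
      if (!nrow(srows)) { bad <- sprintf("no %s evidence", src); break }
      if (!any(srows$status == "complete" & srows$evalue <= evalue_max)) {
        st <- srows$status[1]
        bad <- sprintf("%s domain %s", src,
                       if (any(srows$status == "complete")) "above e-value cutoff" else st)
        break
      }
    }
    if (is.null(bad)) confirmed <- c(confirmed, id) else rejected[[id]] <- bad
  }
  rej <- if (length(rejected)) {
    data.table(protein_id = names(rejected), reason = unlist(rejected))
  } else data.table(protein_id = character(), reason = character())
  list(confirmed = confirmed, rejected = rej)
}

#' Name confirmed genes by chromosomal order
#'
#' Genes are ordered by (homoeologous group number, subgenome letter, start,
#' gene id) and named `<prefix>1 .. <prefix>n`. Genes lacking coordinates are
#' placed after all positioned genes, ordered by id, and flagged.
#'
#' @param genes data.table with `gene_id`, `chrom`, `start` and (from
#'   [parse_chrom_name()]) `group`, `subgenome`.
#' @param prefix name prefix (default `"FAM"`).
#' @return data.table: `gene_id`, `name`, `placed` (logical), in naming order.
#' @export
name_by_position <- function(genes, prefix = "FAM") {
  g <- as.data.table(genes)
  if (anyDuplicated(g$gene_id)) stop("duplicate gene id")
  if (!"group" %in% names(g) || !"subgenome" %in% names(g)) {
    g <- cbind(g, parse_chrom_name(g$chrom))
  }
  g[, placed := !is.na(chrom) & !is.na(start) & !is.na(group)]
  placed_part <- g[placed == TRUE][order(group, subgenome, start, gene_id)]
  unplaced_part <- g[placed == FALSE][order(gene_id)]
  out <- rbindlist(list(placed_part, unplaced_part), fill = TRUE)
  out[, name := paste0(prefix, seq_len(.N))]
  out[, .(gene_id, name, placed)]
}

# Average residue masses (Da) for the 20 canonical amino acids, and the pKa
# table used for isoelectric point; both are configuration, not hard-coded
# into the algorithms.
.aa_masses <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.water_mass <- 18.0153

#' Default pKa table for isoelectric-point calculation
#'
#' Side-chain and terminal pKa values (pH units). Positive groups: N-terminus,
#' Lys, Arg, His; negative groups: C-terminus, Asp, Glu, Cys, Tyr.
#'
#' @return named numeric vector with entries `Nterm`, `Cterm`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`.
#' @export
default_pka <- function() {
  c(Nterm = 8.0, Cterm = 3.1, C = 8.3, D = 3.65, E = 4.25,
    H = 6.0, K = 10.53, R = 12.48, Y = 10.07)
}

.check_residues <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.aa_masses))
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  aa
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch per ionizable group: positive groups contribute
#' `1/(1+10^(pH-pKa))`, negative groups `-1/(1+10^(pKa-pH))`.
#'
#' @param sequence amino-acid string (20 canonical residues).
#' @param ph pH value(s).
#' @param pka pKa table, see [default_pka()].
#' @return net charge, vectorized over `ph`.
#' @export
peptide_charge <- function(sequence, ph, pka = default_pka()) {
  aa <- .check_residues(sequence)
  n <- c(Nterm = 1, Cterm = 1,
         C = sum(aa == "C"), D = sum(aa == "D"), E = sum(aa == "E"),
         H = sum(aa == "H"), K = sum(aa == "K"), R = sum(aa == "R"),
         Y = sum(aa == "Y"))
  pos_groups <- c("Nterm", "K", "R", "H")
  neg_groups <- c("Cterm", "D", "E", "C", "Y")
  vapply(ph, function(p) {
    pos <- sum(n[pos_groups] / (1 + 10^(p - pka[pos_groups])))
    neg <- sum(n[neg_groups] / (1 + 10^(pka[neg_groups] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] where [peptide_charge()] crosses zero, bisecting
#' until |charge| < `tol`.
#'
#' @inheritParams peptide_charge
#' @param tol convergence tolerance on |net charge| (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = default_pka(), tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(sequence, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Protein length, molecular weight and isoelectric point
#'
#' Molecular weight uses average residue masses plus one water; pI comes from
#' [isoelectric_point()].
#'
#' @inheritParams peptide_charge
#' @return list: `length` (residues), `mw_kda`, `pi`.
#' @export
protein_stats <- function(sequence, pka = default_pka()) {
  aa <- .check_residues(sequence)
  mw <- sum(.aa_masses[aa]) + .water_mass
  list(length = length(aa), mw_kda = mw / 1000,
       pi = isoelectric_point(sequence, pka))
}

#' Build the family membership table
#'
#' Convenience wrapper running filter -> domain confirmation -> naming ->
#' protein statistics over parsed inputs.
#'
#' @param hits data.table from [read_hit_table()].
#' @param evidence domain evidence table (see [confirm_domain()]).
#' @param genes gene models from [read_gff3()].
#' @param proteins named character vector (or `AAStringSet`) of protein
#'   sequences keyed by gene id.
#' @param prefix naming prefix.
#' @param evalue_max,identity_min,coverage_min thresholds, see
#'   [filter_candidates()].
#' @return list: `members` (data.table: gene_id, name, chrom, start, length,
#'   mw_kda, pi), `rejected` (from [confirm_domain()]).
#' @export
identify_family <- function(hits, evidence, genes, proteins, prefix = "FAM",
                            evalue_max = 1e-5, identity_min = 60,
                            coverage_min = 0.5) {
  if (inherits(proteins, "XStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  cand <- filter_candidates(hits, evalue_max, identity_min, coverage_min)
  conf <- confirm_domain(cand, evidence)
  genes <- as.data.table(genes)
  fam_genes <- genes[gene_id %in% conf$confirmed]
  extra <- setdiff(conf$confirmed, fam_genes$gene_id)
  if (length(extra)) {
    fam_genes <- rbindlist(list(
      fam_genes,
      data.table(gene_id = extra, chrom = NA_character_, start = NA_integer_)
    ), fill = TRUE)
  }
  names_tab <- name_by_position(fam_genes, prefix = prefix)
  members <- merge(names_tab, fam_genes, by = "gene_id", all.x = TRUE, sort = FALSE)
  stats <- lapply(members$gene_id, function(id) {
    s <- proteins[[id]]
    if (is.null(s) || is.na(s)) return(list(length = NA_integer_, mw_kda = NA_real_, pi = NA_real_))
    protein_stats(s)
  })
  members[, `:=`(length = vapply(stats, function(s) as.integer(s$length), integer(1)),
                 mw_kda = vapply(stats, function(s) as.numeric(s$mw_kda), numeric(1)),
                 pi     = vapply(stats, function(s) as.numeric(s$pi), numeric(1)))]
  ord <- match(names_tab$gene_id, members$gene_id)
  members <- members[ord, .(gene_id, name, placed, chrom, start, length, mw_kda, pi)]
  list(members = members, rejected = conf$rejected)
}
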