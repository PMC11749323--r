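#' Binding free energy of a complex
#'
#' `dG_bind = G_complex - G_A - G_B`: the free energy of the bound complex
#' minus the free energies of the unbound monomers (kcal/mol).
#'
#' @param g_complex,g_a,g_b free energies (kcal/mol).
#' @return binding free energy.
#' @export
binding_energy <- function(g_complex, g_a, g_b) {
  stopifnot(all(is.finite(c(g_complex, g_a, g_b))))
  g_complex - g_a - g_b
}

#' Change in binding free energy upon mutation
#'
#' `ddG = dG_bind(mutant) - dG_bind(wild type)` (kcal/mol); positive values
#' destabilise the complex.
#'
#' @param dg_mut,dg_wt binding free energies (kcal/mol).
#' @return ddG.
#' @export
delta_delta_g <- function(dg_mut, dg_wt) {
  stopifnot(all(is.finite(c(dg_mut, dg_wt))))
  dg_mut - dg_wt
}

#' Deleteriousness rule for mutations
#'
#' A mutation is deleterious iff `|ddG| >= threshold` (default 1.5
#' kcal/mol), boundaries inclusive on both signs.
#'
#' @param ddg numeric ddG values (kcal/mol).
#' @param threshold magnitude cutoff (default 1.5).
#' @return logical vector.
#' @export
classify_deleterious <- function(ddg, threshold = 1.5) {
  stopifnot(all(is.finite(ddg)), threshold > 0)
  abs(ddg) >= threshold
}

#' Read a mutation table
#'
#' Tab-separated with header columns `chain1`, `chain2`, `mutated_chain`,
#' `mutation` (one-letter form, e.g. R419H), `ddg`, and optional
#' `interface`/`deleterious` yes/no columns (preserved as logicals when
#' present). The packaged fixture
#' `system.file("extdata", "mybpc3_actc1_ddg.tsv", package = "cardioreg")`
#' carries 15 curated MYBPC3-ACTC1 records.
#'
#' @param path TSV file.
#' @return data.frame with parsed `wild`, `position`, `mutant` columns.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                          stringsAsFactors = FALSE)
  need <- c("chain1", "chain2", "mutated_chain", "mutation", "ddg")
  if (!all(need %in% names(df))) {
    stop("mutation table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  m <- regmatches(df$mutation, regexec("^([A-Z])([0-9]+)([A-Z])$", df$mutation))
  if (any(lengths(m) != 4L)) {
    stop("unparseable mutation label(s): ",
         paste(df$mutation[lengths(m) != 4L], collapse = ", "), call. = FALSE)
  }
  df$wild <- vapply(m, `[`, "", 2L)
  df$position <- as.integer(vapply(m, `[`, "", 3L))
  df$mutant <- vapply(m, `[`, "", 4L)
  for (col in c("interface", "deleterious")) {
    if (col %in% names(df)) df[[col]] <- tolower(df[[col]]) %in% c("yes", "true", "1")
  }
  df
}

#' Rank mutations by impact magnitude
#'
#' Stable total order: `|ddG|` descending, ties broken by signed ddG
#' descending, then lexicographically by mutation label.
#'
#' @param records mutation data.frame with `ddg` and `mutation`.
#' @param threshold deleteriousness cutoff passed to
#'   [classify_deleterious()].
#' @return records sorted, with a recomputed `deleterious_call` column;
#'   attributes `summary` holds max, min, count and deleterious count.
#' @export
rank_mutations <- function(records, threshold = 1.5) {
  if (nrow(records) == 0L) {
    attr(records, "summary") <- list(n = 0L, max_ddg = NA_real_,
                                     min_ddg = NA_real_, n_deleterious = 0L)
    return(records)
  }
  o <- order(-abs(records$ddg), -records$ddg, records$mutation)
  out <- records[o, , drop = FALSE]
  out$deleterious_call <- classify_deleterious(out$ddg, threshold)
  rownames(out) <- NULL
  attr(out, "summary") <- list(n = nrow(out),
                               max_ddg = max(out$ddg), min_ddg = min(out$ddg),
                               n_deleterious = sum(out$deleterious_call))
  out
}

# Heavy-atom coordinate matrix for a chain (optionally one residue).
chain_coords <- function(atoms, chain, resno = NULL) {
  sel <- atoms$chain == chain
  if (!is.null(resno)) sel <- sel & atoms$resno == resno
  as.matrix(atoms[sel, c("x", "y", "z"), drop = FALSE])
}

# All pairwise Euclidean distances between two coordinate matrices.
cross_dist <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

#' Distance-based interface residue detection
#'
#' A residue of one chain is an interface residue iff any of its heavy
#' atoms lies within `cutoff` angstroms (inclusive) of any heavy atom of
#' the partner chain; the rule is symmetric in the two chains.
#'
#' @param atoms heavy-atom data.frame from [read_pdb_atoms()].
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff distance cutoff in angstroms (default 5.0).
#' @return data.frame: `chain`, `resno`, `resid`, `interface` (logical) for
#'   every residue of both chains.
#' @export
detect_interface <- function(atoms, chain_a, chain_b, cutoff = 5.0) {
  for (ch in c(chain_a, chain_b)) {
    if (!any(atoms$chain == ch)) stop("chain ", ch, " absent from structure",
                                      call. = FALSE)
  }
  a <- atoms[atoms$chain == chain_a, , drop = FALSE]
  b <- atoms[atoms$chain == chain_b, , drop = FALSE]
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
  close <- d <= cutoff
  res <- rbind(
    data.frame(chain = chain_a,
               resno = a$resno, resid = a$resid,
               touch = apply(close, 1, any), stringsAsFactors = FALSE),
    data.frame(chain = chain_b,
               resno = b$resno, resid = b$resid,
               touch = apply(close, 2, any), stringsAsFactors = FALSE)
  )
  out <- stats::aggregate(touch ~ chain + resno + resid, data = res, FUN = any)
  names(out)[names(out) == "touch"] <- "interface"
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Count heavy-atom contacts of a residue
#'
#' Number of heavy atoms (any chain, excluding the residue's own atoms)
#' within `cutoff` angstroms (inclusive) of any heavy atom of the residue.
#'
#' @param atoms heavy-atom data.frame from [read_pdb_atoms()].
#' @param chain chain identifier of the residue.
#' @param resno residue number.
#' @param cutoff contact distance in angstroms (default 4.0).
#' @return integer contact count.
#' @export
count_contacts <- function(atoms, chain, resno, cutoff = 4.0) {
  own <- atoms$chain == chain & atoms$resno == resno
  if (!any(own)) stop("residue ", chain, ":", resno, " absent from structure",
                      call. = FALSE)
  res_xyz <- as.matrix(atoms[own, c("x", "y", "z"), drop = FALSE])
  other <- atoms[!own, , drop = FALSE]
  if (nrow(other) == 0L) return(0L)
  d <- cross_dist(res_xyz, as.matrix(other[, c("x", "y", "z")]))
  sum(apply(d <= cutoff, 2, any))
}
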