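#' Protein structure container
#'
#' Holds a single-chain protein as an ordered residue sequence with one
#' representative 3D coordinate (in Angstrom) per residue.
#'
#' @param id Protein identifier.
#' @param chain Chain identifier the coordinates were taken from.
#' @param sequence Character vector of one-letter residue codes (the 20
#'   standard amino acids; `"X"` marks unknown/nonstandard residues).
#' @param coords Numeric matrix with one row per residue and columns x, y, z.
#'
#' @return An object of class `protein_structure` with fields `id`, `chain`,
#'   `sequence`, `coords` and `n` (residue count).
#' @export
protein_structure <- function(id, chain, sequence, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(sequence) < 1L) stop("protein must contain at least one residue")
  if (nrow(coords) != length(sequence)) {
    stop(sprintf("sequence length (%d) does not match coordinate rows (%d)",
                 length(sequence), nrow(coords)))
  }
  if (ncol(coords) != 3L) stop("coords must have three columns (x, y, z)")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  structure(
    list(id = as.character(id), chain = as.character(chain),
         sequence = as.character(sequence), coords = unname(coords),
         n = length(sequence)),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s chain %s: %d residues\n", x$id, x$chain, x$n))
  invisible(x)
}

#' Parse a PDB coordinate file into a protein structure
#'
#' Reads a PDB-format file, selects one chain and one representative atom per
#' residue (C-alpha by default), and returns the residue sequence with its
#' coordinates. Residues that lack the representative atom are dropped with a
#' warning and the sequence is shortened consistently. Nonstandard residues
#' with a common parent (e.g. selenomethionine) are mapped to the parent
#' one-letter code; anything else becomes `"X"` but keeps its coordinates.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier. If `NULL` and the file holds exactly one
#'   chain, that chain is used; with several chains an explicit choice is
#'   required.
#' @param atom Representative atom name, `"CA"` (default) or `"CB"`.
#' @param id Identifier for the returned structure; defaults to the file stem.
#'
#' @return A [protein_structure()].
#' @export
parse_structure <- function(path, chain = NULL, atom = c("CA", "CB"), id = NULL) {
  atom <- match.arg(atom)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  chains <- sort(unique(atoms$chain))
  if (is.null(chain)) {
    if (length(chains) == 1L) chain <- chains
    else stop("multiple chains present (", paste(chains, collapse = ", "),
              "); specify `chain`")
  }
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain, paste(chains, collapse = ", ")))
  }
  ch <- atoms[atoms$chain == chain & atoms$type == "ATOM", , drop = FALSE]
  # residues in file order; key on (resno, insert) to keep insertion codes apart
  ins <- ifelse(is.na(ch$insert), "", ch$insert)
  key <- paste(ch$resno, ins, sep = "_")
  res_keys <- unique(key)
  # first altloc only: keep the first matching atom record per residue
  idx <- vapply(res_keys, function(k) {
    hits <- which(key == k & ch$elety == atom)
    if (length(hits) == 0L) NA_integer_ else hits[1L]
  }, integer(1))
  dropped <- sum(is.na(idx))
  if (dropped > 0L) {
    warning(sprintf("%d residue(s) lack atom %s and were dropped", dropped, atom))
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0L) {
    stop(sprintf("no residues with atom %s retained on chain %s", atom, chain))
  }
  aa3 <- ch$resid[idx]
  aa1 <- suppressWarnings(bio3d::aa321(aa3))
  aa1[is.na(aa1) | !aa1 %in% AA_ALPHABET] <- "X"
  coords <- cbind(ch$x[idx], ch$y[idx], ch$z[idx])
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  protein_structure(id = id, chain = chain, sequence = aa1, coords = coords)
}

#' Read protein sequences from a FASTA file
#'
#' Sequence-only entry point for workflows without coordinates.
#'
#' @param path Path to a FASTA file.
#' @return Named list of character vectors of one-letter residue codes.
#' @export
read_sequences <- function(path) {
  fas <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  lapply(fas, function(s) toupper(as.character(s)))
}

#' Residue contact graph
#'
#' Builds the undirected residue contact graph of a protein: vertices are
#' residues and an edge joins residues `i != j` whose representative-atom
#' Euclidean distance is strictly below `threshold`.
#'
#' @param struct A [protein_structure()].
#' @param threshold Contact distance threshold in Angstrom (default 10.0,
#'   strict `<` comparison).
#'
#' @return An object of class `contact_graph` with fields `n`, `adjacency`
#'   (n x n binary symmetric, zero diagonal), `degrees`, `edges` (data frame
#'   of `i < j` vertex pairs with distances) and `threshold`.
#' @export
build_contact_graph <- function(struct, threshold = 10.0) {
  stopifnot(inherits(struct, "protein_structure"))
  if (threshold <= 0) stop("threshold must be positive")
  n <- struct$n
  if (n == 0L) stop("empty structure")
  D <- as.matrix(stats::dist(struct$coords))
  A <- (D < threshold) * 1
  diag(A) <- 0
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      distance = D[ut])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(n = n, adjacency = unname(A), degrees = unname(rowSums(A)),
         edges = edges, threshold = threshold),
    class = "contact_graph"
  )
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d vertices, %d edges (threshold %.1f A)\n",
              x$n, nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write a contact graph as an edge-list TSV
#'
#' One row per undirected edge: 1-based vertex indices `i`, `j` and the
#' inter-residue distance in Angstrom.
#'
#' @param graph A `contact_graph`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_contact_graph <- function(graph, path) {
  stopifnot(inherits(graph, "contact_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
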