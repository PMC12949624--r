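#' Average residue-mass table for peptide mass calculation
#'
#' Constants used by [peptide_mass()]: average (not monoisotopic) residue
#' masses in Da for the 20 canonical amino acids, the mass of water, and the
#' mass deltas of the supported modifications. N-terminal acetylation replaces
#' an amine hydrogen with an acetyl group (+42.0367 Da); C-terminal amidation
#' replaces the terminal hydroxyl with an amine (-0.9847 Da); side-chain
#' lactam formation (Lys amine condensing with Asp/Glu carboxyl) loses one
#' water (-18.0153 Da). Counter-ions (e.g. TFA salts) are not included.
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water`, `acetyl`, `amide` and `lactam` (Da).
#' @examples
#' mass_table()$residues[["G"]]
#' @export
mass_table <- function() {
  tab <- list(
    residues = c(
      G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
      T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
      D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
      H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
    ),
    water  = 18.0153,
    acetyl = 42.0367,
    amide  = -0.9847,
    lactam = -18.0153
  )
  stopifnot(all(tab$residues > 0), tab$water > 0,
            isTRUE(all.equal(tab$lactam, -tab$water)))
  tab
}

# residues able to form a side-chain lactam: one amine donor, one carboxyl
.lactam_amine    <- "K"
.lactam_carboxyl <- c("D", "E")

.is_lactam_pair <- function(res_i, res_j) {
  (res_i %in% .lactam_amine && res_j %in% .lactam_carboxyl) ||
    (res_j %in% .lactam_amine && res_i %in% .lactam_carboxyl)
}

#' Construct a peptide object
#'
#' A `peptide` records a sequence of one-letter canonical amino-acid codes,
#' terminal modifications, and an optional side-chain lactam staple joining a
#' lysine to an aspartate or glutamate.
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @param n_term `"free"` or `"acetyl"`.
#' @param c_term `"free"` or `"amide"`.
#' @param staple `NULL`, or an integer vector of two distinct 1-based residue
#'   positions joined by a lactam bond; one position must hold K and the other
#'   D or E.
#' @param label Free-text identifier.
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("GGRRGLVCGV", n_term = "acetyl", c_term = "amide")
#' @export
peptide <- function(sequence, n_term = c("free", "acetyl"),
                    c_term = c("free", "amide"), staple = NULL, label = "") {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  known <- names(mass_table()$residues)
  bad <- setdiff(res, known)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (!is.null(staple)) {
    staple <- as.integer(staple)
    if (length(staple) != 2L || anyNA(staple))
      stop("staple must give two residue positions")
    if (staple[1] == staple[2])
      stop("staple positions must be distinct")
    if (any(staple < 1L) || any(staple > length(res)))
      stop("staple position out of range")
    if (!.is_lactam_pair(res[staple[1]], res[staple[2]]))
      stop("staple residues chemically incompatible: need one of K and one of D/E, got ",
           res[staple[1]], "/", res[staple[2]])
  }
  structure(list(sequence = sequence, n_term = n_term, c_term = c_term,
                 staple = staple, label = label),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("Peptide", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  ", format_peptide(x), "\n", sep = "")
  cat("  length ", nchar(x$sequence),
      ", average mass ", sprintf("%.2f", peptide_mass(x)$mass), " Da\n", sep = "")
  invisible(x)
}

#' Parse a peptide specification string
#'
#' The dialect is `"Ac-SEQ-NH2"` with an optional `"staple=i,j"` suffix
#' (whitespace-separated); a bare `"SEQ"` means free termini. `Ac-` and
#' `-NH2` may be used independently.
#'
#' @param spec Character scalar, e.g. `"Ac-GGRRGLVCGV-NH2"` or
#'   `"Ac-RKEYLEELDGGR-NH2 staple=2,6"`.
#' @param label Optional identifier stored on the result.
#' @return A [peptide()].
#' @seealso [format_peptide()] for the inverse.
#' @examples
#' parse_peptide("Ac-GGRRGLVCGV-NH2")
#' @export
parse_peptide <- function(spec, label = "") {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  if (length(parts) < 1L || !nzchar(parts[1])) stop("empty peptide spec")
  body <- parts[1]
  staple <- NULL
  if (length(parts) > 1L) {
    extra <- parts[-1]
    m <- grepl("^staple=", extra)
    if (!all(m)) stop("unrecognised token(s) in peptide spec: ",
                      paste(extra[!m], collapse = " "))
    if (sum(m) > 1L) stop("multiple staple specifications")
    ij <- strsplit(sub("^staple=", "", extra[m]), ",")[[1]]
    if (length(ij) != 2L || anyNA(suppressWarnings(as.integer(ij))))
      stop("malformed staple: expected staple=i,j")
    staple <- as.integer(ij)
  }
  n_term <- "free"; c_term <- "free"
  if (grepl("^Ac-", body)) { n_term <- "acetyl"; body <- sub("^Ac-", "", body) }
  if (grepl("-NH2$", body)) { c_term <- "amide"; body <- sub("-NH2$", "", body) }
  peptide(body, n_term = n_term, c_term = c_term, staple = staple, label = label)
}

#' Format a peptide back to its specification string
#'
#' Inverse of [parse_peptide()]; `parse_peptide(format_peptide(p))` recovers
#' `p` up to its label.
#'
#' @param p A [peptide()].
#' @return Character scalar in the spec dialect.
#' @export
format_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  out <- p$sequence
  if (p$n_term == "acetyl") out <- paste0("Ac-", out)
  if (p$c_term == "amide") out <- paste0(out, "-NH2")
  if (!is.null(p$staple))
    out <- paste0(out, " staple=", p$staple[1], ",", p$staple[2])
  out
}

#' Average molecular mass of a peptide
#'
#' Sums average residue masses, adds one water for the free chain, applies
#' the terminal-modification deltas, and subtracts one water if a lactam
#' staple is present. The rounded value uses round-half-up to the nearest
#' integer Da, the convention used for tabulated peptide MWs.
#'
#' @param p A [peptide()].
#' @param table A mass table as returned by [mass_table()].
#' @return List with `mass` (Da, full precision) and `rounded` (integer Da).
#' @examples
#' peptide_mass(parse_peptide("Ac-GGRRGLVCGV-NH2"))$rounded  # 1014
#' @export
peptide_mass <- function(p, table = mass_table()) {
  stopifnot(inherits(p, "peptide"))
  res <- strsplit(p$sequence, "")[[1]]
  m <- sum(table$residues[res]) + table$water
  if (p$n_term == "acetyl") m <- m + table$acetyl
  if (p$c_term == "amide") m <- m + table$amide
  if (!is.null(p$staple)) m <- m + table$lactam
  list(mass = m, rounded = as.integer(floor(m + 0.5)))
}

#' Alanine-scan variants of a peptide
#'
#' Replaces the residue at each requested position with alanine, one variant
#' per position; termini, staple and label are propagated (labels gain an
#' `"_<pos>A"` suffix). Scanning a position that already holds alanine
#' returns the unchanged sequence.
#'
#' @param p A [peptide()].
#' @param positions Integer vector of 1-based positions.
#' @return List of [peptide()] objects, one per position.
#' @export
alanine_scan <- function(p, positions) {
  stopifnot(inherits(p, "peptide"))
  positions <- as.integer(positions)
  n <- nchar(p$sequence)
  if (any(positions < 1L) || any(positions > n))
    stop("alanine-scan position out of range 1..", n)
  lapply(positions, function(i) {
    res <- strsplit(p$sequence, "")[[1]]
    orig <- res[i]
    res[i] <- "A"
    peptide(paste(res, collapse = ""), n_term = p$n_term, c_term = p$c_term,
            staple = p$staple,
            label = if (nzchar(p$label)) paste0(p$label, "_", orig, i, "A") else
              paste0(orig, i, "A"))
  })
}

#' Contiguous fragment of a peptide
#'
#' @param p A [peptide()].
#' @param start,end Inclusive 1-based bounds.
#' @param n_term,c_term Terminal modifications of the fragment; defaults keep
#'   the parent's (fragments are synthesised with the same capping chemistry).
#' @return A [peptide()]; any staple is dropped unless both stapled positions
#'   fall inside the fragment (then re-indexed).
#' @export
peptide_fragment <- function(p, start, end, n_term = p$n_term, c_term = p$c_term) {
  stopifnot(inherits(p, "peptide"))
  start <- as.integer(start); end <- as.integer(end)
  n <- nchar(p$sequence)
  if (start < 1L || end > n || start > end)
    stop("fragment bounds out of range or inverted: ", start, "..", end,
         " for length ", n)
  sub <- substr(p$sequence, start, end)
  staple <- NULL
  if (!is.null(p$staple) && all(p$staple >= start) && all(p$staple <= end))
    staple <- p$staple - start + 1L
  peptide(sub, n_term = n_term, c_term = c_term, staple = staple, label = p$label)
}

#' Introduce a side-chain lactam staple
#'
#' Substitutes the residues at positions `i` and `j` (by default with K and E,
#' the Lys-Glu pair) and records a lactam bond between them. The mass of the
#' stapled peptide equals the substituted linear peptide minus one water.
#'
#' @param p A [peptide()].
#' @param i,j Distinct 1-based positions.
#' @param sub_i,sub_j Residues substituted at `i` and `j`; must form a valid
#'   lactam pair (one K, one of D/E).
#' @return A stapled [peptide()].
#' @export
peptide_staple <- function(p, i, j, sub_i = "K", sub_j = "E") {
  stopifnot(inherits(p, "peptide"))
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("staple positions must be distinct")
  n <- nchar(p$sequence)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("staple position out of range")
  if (!.is_lactam_pair(sub_i, sub_j))
    stop("invalid lactam pair: ", sub_i, "/", sub_j)
  res <- strsplit(p$sequence, "")[[1]]
  res[i] <- sub_i; res[j] <- sub_j
  peptide(paste(res, collapse = ""), n_term = p$n_term, c_term = p$c_term,
          staple = c(i, j), label = p$label)
}

#' Tabulate peptides with rounded molecular weights
#'
#' Builds a table in the style of a designed-peptide summary: one row per
#' specification string with label, sequence, modifications and rounded
#' average MW. Optionally written as TSV.
#'
#' @param specs Character vector of peptide spec strings.
#' @param labels Optional unique labels (default `pep1`, `pep2`, ...).
#' @param file Optional path; if given the table is written as TSV.
#' @return A data.frame with columns `label`, `sequence`, `n_term`, `c_term`,
#'   `staple`, `mw_da`.
#' @export
peptide_table <- function(specs, labels = NULL, file = NULL) {
  stopifnot(is.character(specs))
  if (is.null(labels)) labels <- sprintf("pep%d", seq_along(specs))
  if (length(labels) != length(specs)) stop("labels must match specs in length")
  if (anyDuplicated(labels)) stop("duplicate peptide labels")
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    p <- tryCatch(parse_peptide(specs[k], label = labels[k]),
                  error = function(e)
                    stop("row ", k, " (", labels[k], "): ", conditionMessage(e),
                         call. = FALSE))
    rows[[k]] <- data.frame(
      label = labels[k], sequence = p$sequence, n_term = p$n_term,
      c_term = p$c_term,
      staple = if (is.null(p$staple)) "" else paste(p$staple, collapse = ","),
      mw_da = peptide_mass(p)$rounded,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (length(specs) == 0L)
    out <- data.frame(label = character(), sequence = character(),
                      n_term = character(), c_term = character(),
                      staple = character(), mw_da = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
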