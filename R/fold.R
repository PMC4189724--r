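#' Energy parameters of the built-in folding model
#'
#' The default folding engine scores pseudoknot-free secondary structures with
#' published nearest-neighbor stacking free energies for Watson-Crick and G:U
#' pairs, and loop penalties linear in loop size (a deliberate simplification
#' of the full tabulated loop model). All energies are kcal/mol.
#'
#' @return a list with elements `stack` (6x6 matrix, rows = closing pair,
#'   columns = inner pair, order AU/UA/CG/GC/GU/UG), `hairpin` (intercept,
#'   per-unpaired-base slope), `internal` (intercept, slope), `multi`
#'   (intercept, per-branch, per-unpaired-base), `minloop` (minimum hairpin
#'   loop), `maxloop` (maximum internal/bulge loop size).
#' @export
fold_energy_params <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU    UA    CG    GC    GU    UG
            -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
            -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
            -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
            -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # outer GC
            -1.3, -1.4, -2.5, -2.1, -0.5,  1.3,  # outer GU
            -1.0, -0.6, -1.5, -1.4,  0.3, -0.5   # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(stack = stack,
       hairpin = c(3.0, 0.3),
       internal = c(2.0, 0.5),
       multi = c(3.4, 0.4, 0.1),
       minloop = 3L,
       maxloop = 30L)
}

#' Fold a sequence into its minimum-free-energy hairpin structure
#'
#' Predicts a pseudoknot-free secondary structure and its minimum folding free
#' energy (MFE) with the built-in deterministic nearest-neighbor model, or an
#' optional external backend. U and T spellings are equivalent. A sequence
#' with no complementary stretches folds to the open structure with MFE 0;
#' the reported MFE is always <= 0 because the open chain has energy zero.
#'
#' @param sequence a single RNA/DNA sequence (A/C/G/U/T).
#' @param params energy parameters, see [fold_energy_params()].
#' @param backend optional plug-in: a `function(sequence)` returning
#'   `list(structure=, mfe=)` (e.g. wrapping an external folding program).
#'   The built-in model is the default.
#' @return list with `structure` (dot-bracket string) and `mfe` (kcal/mol).
#' @examples
#' fold_hairpin("AAAAAAAAAA")              # no pairs: all dots, mfe 0
#' fold_hairpin(paste0("GCGCGCGC", "AAAA", "GCGCGCGC"))
#' @export
fold_hairpin <- function(sequence, params = fold_energy_params(),
                         backend = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_dna <- norm_dna(sequence, allow_n = FALSE)
  if (!is.null(backend)) {
    res <- backend(sequence)
    stopifnot(is.list(res), !is.null(res$structure), !is.null(res$mfe))
    return(list(structure = res$structure, mfe = as.numeric(res$mfe)))
  }
  res <- .fold_mfe_cpp(seq_dna, params$stack,
                       params$hairpin[1], params$hairpin[2],
                       params$internal[1], params$internal[2],
                       params$multi[1], params$multi[2], params$multi[3],
                       as.integer(params$minloop), as.integer(params$maxloop))
  list(structure = res$structure, mfe = res$mfe)
}

#' Parse a dot-bracket string into a base-pair table
#'
#' @param structure dot-bracket string.
#' @return integer vector `partner` of the same length: `partner[i]` is the
#'   1-based position paired with i, or NA if unpaired.
#' @export
pairing_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket structure: ", ch[i])
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  partner
}

#' Free energy of a given structure under the built-in model
#'
#' Evaluates a dot-bracket structure by loop decomposition: stacking terms for
#' helical pair steps, linear hairpin / internal / bulge loop penalties, and a
#' linear multiloop penalty. External (unpaired, outside any pair) bases are
#' free. This is the same scoring the folding engine minimizes.
#'
#' @param sequence the sequence (A/C/G/U/T).
#' @param structure dot-bracket string of the same length.
#' @param params energy parameters, see [fold_energy_params()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure,
                             params = fold_energy_params()) {
  s <- strsplit(norm_dna(sequence, allow_n = FALSE), "")[[1]]
  partner <- pairing_table(structure)
  if (length(s) != length(partner)) stop("sequence/structure length mismatch")
  pair_name <- function(i, j) {
    p <- chartr("T", "U", paste0(s[i], s[j]))
    if (!p %in% rownames(params$stack)) {
      stop("non-canonical pair ", p, " at ", i, ":", j)
    }
    p
  }
  energy <- 0
  opens <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in opens) {
    j <- partner[i]
    if (j - i - 1 < params$minloop && !any(!is.na(partner[(i + 1):(j - 1)]))) {
      stop("hairpin loop below minimum size at ", i, ":", j)
    }
    # children: pairs immediately interior to (i, j)
    k <- i + 1L
    children <- list()
    unpaired <- 0L
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        if (is.na(partner[k])) unpaired <- unpaired + 1L else
          stop("crossing (pseudoknotted) structure")
        k <- k + 1L
      }
    }
    nb <- length(children)
    if (nb == 0L) {
      energy <- energy + params$hairpin[1] + params$hairpin[2] * (j - i - 1)
    } else if (nb == 1L) {
      p <- children[[1]][1]; q <- children[[1]][2]
      n1 <- p - i - 1L; n2 <- j - q - 1L
      if (n1 + n2 == 0L) {
        energy <- energy + params$stack[pair_name(i, j), pair_name(p, q)]
      } else {
        energy <- energy + params$internal[1] + params$internal[2] * (n1 + n2)
      }
    } else {
      energy <- energy + params$multi[1] +
        params$multi[2] * (nb + 1) + params$multi[3] * unpaired
    }
  }
  energy
}
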