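# Independent oracles for the folding engine.
#
# enumerate_pairsets() lists every pseudoknot-free set of canonical pairs
# (minimum hairpin loop respected) by explicit recursion; oracle_energy()
# scores a pair set by its own loop decomposition. Both are written
# independently of the package implementation and share only the numeric
# energy table.

can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

enumerate_pairsets <- function(seq, minloop = 3L) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(s)
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity)             # i unpaired
    if (i + minloop + 1L <= j) {
      for (k in (i + minloop + 1L):j) {
        if (can_pair(s[i], s[k])) {
          inner <- rec(i + 1L, k - 1L)
          outer <- rec(k + 1L, j)
          for (a in inner) for (b in outer) {
            out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# loop-decomposition energy of a pair set, written from scratch
oracle_energy <- function(seq, pairs, params) {
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  if (!length(pairs)) return(0)
  open <- vapply(pairs, `[`, integer(1), 1L)
  close <- vapply(pairs, `[`, integer(1), 2L)
  partner <- rep(NA_integer_, length(s))
  partner[open] <- close
  partner[close] <- open
  pname <- function(i, j) chartr("T", "U", paste0(s[i], s[j]))
  total <- 0
  for (idx in seq_along(open)) {
    i <- open[idx]; j <- close[idx]
    # direct children of (i, j)
    kids <- list(); unpaired <- 0L; k <- i + 1L
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(kids) == 0L) {
      total <- total + params$hairpin[1] + params$hairpin[2] * (j - i - 1L)
    } else if (length(kids) == 1L) {
      p <- kids[[1]][1]; q <- kids[[1]][2]
      n1 <- p - i - 1L; n2 <- j - q - 1L
      total <- total + if (n1 + n2 == 0L) {
        params$stack[pname(i, j), pname(p, q)]
      } else {
        params$internal[1] + params$internal[2] * (n1 + n2)
      }
    } else {
      total <- total + params$multi[1] +
        params$multi[2] * (length(kids) + 1L) + params$multi[3] * unpaired
    }
  }
  total
}

oracle_mfe <- function(seq, params = fold_energy_params()) {
  sets <- enumerate_pairsets(seq, params$minloop)
  min(c(0, vapply(sets, function(p) oracle_energy(seq, p, params),
                  numeric(1))))
}

# brute-force rescoring of every window (the scanner oracle)
brute_force_scan <- function(mirna, transcript, scheme = target_scheme(),
                             gaps = TRUE) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  rows <- list()
  widths <- if (gaps) c(L, L - 1L, L + 1L) else L
  for (w in widths) {
    if (n < w) next
    gap_in <- if (w == L) "none" else if (w < L) "mirna" else "target"
    for (start in seq_len(n - w + 1L)) {
      al <- score_target(mirna, substr(transcript, start, start + w - 1L),
                         scheme, gap_in = gap_in)
      if (al$score <= scheme$cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(start = start, width = w,
                                                score = al$score)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), width = integer(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$width), , drop = FALSE]
}
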