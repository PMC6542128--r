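# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package code they check.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# pair admissibility identical in meaning to the model contract, written out
admissible_oracle <- function(ch, i, j, model) {
  type <- c(GC = "GC", CG = "GC", AU = "AU", UA = "AU",
            GU = "GU", UG = "GU")[paste0(ch[i], ch[j])]
  !is.na(type) && (model$allow_gu || type != "GU") && (j - i) > model$theta
}

# structure enumerator decomposing on the LEFTMOST position (the package's
# enumerate_structures decomposes on the rightmost), returning canonical
# "i:j,i:j" key strings so structure sets can be compared exactly
enum_leftmost <- function(s, model = energy_model()) {
  seq <- as_rna_sequence(s)
  ch <- strsplit(seq$residues, "")[[1]]
  n <- seq$length
  rec <- function(i, j) {
    if (i > j) return(list(integer(0)))
    out <- lapply(rec(i + 1, j), identity)               # i unpaired
    if (j - i > model$theta) {
      for (k in (i + model$theta + 1):j) {
        if (!admissible_oracle(ch, i, k, model)) next
        inner <- rec(i + 1, k - 1)
        outer <- rec(k + 1, j)
        for (a in inner) for (b in outer) {
          out <- c(out, list(c(i, k, a, b)))
        }
      }
    }
    out
  }
  lapply(rec(1, n), function(v) {
    if (length(v) == 0) return("")
    m <- matrix(v, ncol = 2, byrow = TRUE)
    paste(sort(paste(m[, 1], m[, 2], sep = ":")), collapse = ",")
  })
}

structure_key <- function(pairs) {
  if (nrow(pairs) == 0) return("")
  paste(sort(paste(pairs$i, pairs$j, sep = ":")), collapse = ",")
}

# Boltzmann statistics computed directly from an exhaustive structure list
boltzmann_oracle <- function(s, model = energy_model()) {
  seq <- as_rna_sequence(s)
  ch <- strsplit(seq$residues, "")[[1]]
  structs <- enumerate_structures(seq, model)
  energy_of <- function(st) {
    if (nrow(st) == 0) return(0)
    type <- c(GC = "GC", CG = "GC", AU = "AU", UA = "AU",
              GU = "GU", UG = "GU")[paste0(ch[st$i], ch[st$j])]
    sum(model$pair_energy[type])
  }
  energies <- vapply(structs, energy_of, numeric(1))
  ktr <- (273.15 + model$temperature_c) / (273.15 + 37)
  wts <- exp(-energies / ktr)
  Q <- sum(wts)
  freq <- new.env(parent = emptyenv())
  for (k in seq_along(structs)) {
    st <- structs[[k]]
    if (nrow(st) == 0) next
    for (r in seq_len(nrow(st))) {
      key <- paste(st$i[r], st$j[r], sep = ":")
      freq[[key]] <- (if (is.null(freq[[key]])) 0 else freq[[key]]) + wts[k]
    }
  }
  p_of <- function(i, j) {
    v <- freq[[paste(i, j, sep = ":")]]
    if (is.null(v)) 0 else v / Q
  }
  list(Q = Q, p_of = p_of, pair_keys = ls(freq),
       min_energy = min(energies), structures = structs,
       energies = energies)
}

# brute-force local alignment optimum: global alignment score (memoised
# top-down recursion) maximised over all substring pairs, empty included
bf_local_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  glob <- function(x, y) {
    nx <- length(x); ny <- length(y)
    memo <- array(NA_real_, c(nx + 1, ny + 1))
    rec <- function(i, j) {
      if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
      v <- if (i == 0 && j == 0) {
        0
      } else {
        cand <- -Inf
        if (i > 0 && j > 0) {
          cand <- max(cand, rec(i - 1, j - 1) +
                        if (x[i] == y[j]) scheme$match else scheme$mismatch)
        }
        if (i > 0) cand <- max(cand, rec(i - 1, j) + scheme$gap)
        if (j > 0) cand <- max(cand, rec(i, j - 1) + scheme$gap)
        cand
      }
      memo[i + 1, j + 1] <<- v
      v
    }
    rec(nx, ny)
  }
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A)) {
    for (j1 in seq_along(B)) for (j2 in j1:length(B)) {
      best <- max(best, glob(A[i1:i2], B[j1:j2]))
    }
  }
  best
}

# random valid dot-bracket string with minimum hairpin size 3
random_db <- function(n) {
  rec <- function(m) {
    if (m < 5) return(strrep(".", m))
    if (stats::runif(1) < 0.4) {
      k <- sample(3:(m - 2), 1)
      paste0("(", rec(k), ")", rec(m - k - 2))
    } else {
      paste0(".", rec(m - 1))
    }
  }
  rec(n)
}

# parse SVG text into an xml2 doc with namespaces stripped for easy xpath
read_svg <- function(svg) {
  doc <- xml2::read_xml(unclass(svg))
  xml2::xml_ns_strip(doc)
  doc
}
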