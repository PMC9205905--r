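# Independent oracles and fixture builders. Each oracle is implemented from
# first principles, separately from the package code paths it checks.

# ---- symmetric 3x3 eigen-decomposition via the characteristic polynomial ----
# Largest eigenvalue from the trigonometric closed form for the cubic
# det(A - lambda I) = 0; eigenvector from cross products of rows of
# (A - lambda I).
oracle_principal_axis <- function(A) {
  stopifnot(all(dim(A) == c(3, 3)), max(abs(A - t(A))) < 1e-12)
  q <- sum(diag(A)) / 3
  B <- A - q * diag(3)
  p2 <- sum(B^2) / 6
  if (p2 < 1e-30) return(list(value = q, vector = c(1, 0, 0)))
  p <- sqrt(p2)
  r <- det(B / p) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  lambda <- q + 2 * p * cos(phi)        # largest root
  M <- A - lambda * diag(3)
  cr <- rbind(pracma_cross(M[1, ], M[2, ]),
              pracma_cross(M[1, ], M[3, ]),
              pracma_cross(M[2, ], M[3, ]))
  norms <- sqrt(rowSums(cr^2))
  v <- cr[which.max(norms), ]
  list(value = lambda, vector = v / sqrt(sum(v^2)))
}
pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# ---- memoized-recursion global alignment (match +1, mismatch 0, gap -1) ----
# Same declared tie-break as the package (diagonal > up > left), but written
# as a top-down recursion rather than an iterative matrix fill.
oracle_align <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- new.env(parent = emptyenv())
  score <- function(i, j) {
    if (i == 0L) return(-j)
    if (j == 0L) return(-i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- max(score(i - 1L, j - 1L) + (a[i] == b[j]),
             score(i - 1L, j) - 1,
             score(i, j - 1L) - 1)
    memo[[key]] <- s
    s
  }
  i <- n; j <- m; pairs <- NULL
  while (i > 0L && j > 0L) {
    s <- score(i, j)
    if (s == score(i - 1L, j - 1L) + (a[i] == b[j])) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1L; j <- j - 1L
    } else if (s == score(i - 1L, j) - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairs = pairs, score = score(n, m))
}

# ---- exhaustive simple-path search for the max-product pathway ----
# Depth-first enumeration of every simple path from source to any sink;
# ties (relative 1e-9) broken by the lexicographically smaller node sequence.
oracle_best_path <- function(edges, source, sinks) {
  nbr <- function(u) {
    k <- which(edges$donor_id == u | edges$acceptor_id == u)
    data.frame(v = ifelse(edges$donor_id[k] == u, edges$acceptor_id[k],
                          edges$donor_id[k]),
               w = edges$weight[k], stringsAsFactors = FALSE)
  }
  lex_lt <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  best <- list(product = -Inf, path = NULL)
  walk <- function(u, visited, prod_w) {
    if (u %in% sinks) {
      if (is.null(best$path)) {
        best <<- list(product = prod_w, path = visited)
      } else {
        tol <- 1e-9 * max(prod_w, best$product)
        if (prod_w > best$product + tol ||
            (abs(prod_w - best$product) <= tol && lex_lt(visited, best$path)))
          best <<- list(product = prod_w, path = visited)
      }
      return(invisible())
    }
    nb <- nbr(u)
    for (k in seq_len(nrow(nb))) {
      v <- nb$v[k]
      if (v %in% visited) next
      walk(v, c(visited, v), prod_w * nb$w[k])
    }
  }
  walk(source, source, 1)
  if (is.null(best$path)) list(status = "disconnected") else
    list(status = "ok", path = best$path, product = best$product)
}

# ---- brute-force O(n^2) distance-gated pair enumeration ----
oracle_pair_set <- function(centroids, ids, cutoff) {
  out <- character()
  n <- nrow(centroids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
    if (r <= cutoff)
      out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
  }
  sort(out)
}

# ---- geometry helpers ----
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# ---- in-memory fixture builders ----
# A free-standing point chromophore with prescribed centroid and dipole;
# the conjugated coordinates are a 5-atom collinear run along the dipole so
# package-side dipole assignment would reproduce `direction`.
point_chromophore <- function(id, centroid, direction, cylinder = "X",
                              magnitude = 1) {
  direction <- direction / sqrt(sum(direction^2))
  offs <- 0.5 * ((1:5) - 3)
  coords <- t(vapply(offs, function(s) centroid + s * direction, numeric(3)))
  rownames(coords) <- paste0("A", 1:5)
  structure(list(
    id = list(cylinder = cylinder, unit_index = 1L, role = "ApcA",
              subunit = "alpha", descriptor = "a1", attach_residue = 1L,
              tentative = FALSE, rendered = id),
    parent_chain = "A", resno = 1L, ligand_code = "CYC",
    conjugated_coords = coords, centroid = centroid,
    dipole = list(direction = direction, magnitude = magnitude),
    incomplete = FALSE, attach_fallback = TRUE), class = "chromophore")
}

# A CA-only single-chain model from a one-letter sequence and coordinates.
seq_model <- function(chain, seq1, coords, identifier = "seqfix") {
  aa <- strsplit(seq1, "")[[1]]
  atoms <- data.frame(chain = chain, resno = seq_along(aa), insert = "",
                      resid = bio3d::aa123(aa), elety = "CA", elesy = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      occ = 1, het = FALSE, stringsAsFactors = FALSE)
  pbsfret:::new_structure_model(identifier, atoms, "pdb")
}

helix_coords <- function(n, offset = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  cbind(2.3 * cos(i * 1.7) + offset[1],
        2.3 * sin(i * 1.7) + offset[2],
        1.5 * i + offset[3])
}
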