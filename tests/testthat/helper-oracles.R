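# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's spatial-indexing code paths: plain O(n^2) distance
# matrices, union-find clustering, and closed-form ray-sphere intersection
# over large random direction sets.

# O(n^2) neighbour-count oracle
oracle_neighbor_counts <- function(points, radius) {
  d <- as.matrix(dist(points))
  rowSums(d > 0 & d <= radius)
}

# union-find single-linkage clustering oracle (joins pairs strictly closer
# than dthresh)
oracle_union_find <- function(points, dthresh) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d <- as.matrix(dist(points))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] < dthresh) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# normalized cluster signature for comparing two labelings up to relabeling
cluster_signature <- function(labels) {
  groups <- split(seq_along(labels), labels)
  sig <- vapply(groups, function(g) paste(sort(g), collapse = ","), "")
  sort(unname(sig))
}

# Dense-ray enclosure oracle: exact first-entry ray-sphere intersection over
# `n_rays` random directions (chunked, vectorized).
oracle_enclosure <- function(point, atoms_xyz, radii, maxdist, n_rays = 1e6,
                             seed = 42) {
  set.seed(seed)
  rel <- sweep(atoms_xyz, 2, point)
  a2 <- rowSums(rel^2)
  r2 <- radii^2
  keep <- a2 <= (maxdist + max(radii))^2
  rel <- rel[keep, , drop = FALSE]; a2 <- a2[keep]; r2 <- r2[keep]
  if (!nrow(rel)) return(0)
  if (any(a2 <= r2)) return(1)
  hits <- 0
  done <- 0
  chunk <- 20000L
  while (done < n_rays) {
    m <- min(chunk, n_rays - done)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    b <- u %*% t(rel)                      # m x natoms
    disc <- matrix(r2, m, length(r2), byrow = TRUE) -
      (matrix(a2, m, length(a2), byrow = TRUE) - b^2)
    ok <- b > 0 & disc >= 0
    t_entry <- b - sqrt(pmax(disc, 0))
    hit <- ok & t_entry >= 0 & t_entry <= maxdist
    hits <- hits + sum(rowSums(hit) > 0)
    done <- done + m
  }
  hits / n_rays
}

# brute-force kernel sum oracle for the phobic/philic fields
oracle_kernel_sum <- function(point, atoms_xyz, weights, cutoff) {
  d <- sqrt(colSums((t(atoms_xyz) - point)^2))
  sel <- d < cutoff
  sum(weights[sel] * (1 - d[sel] / cutoff)^2)
}

# write a small multi-chain test protein in PDB format, with optional waters
# and het groups; returns the path
write_mini_protein <- function(path, chains = c("A", "B"), with_water = FALSE,
                               het = NULL, ca_only = FALSE) {
  tmpl <- utils::read.delim(system.file("extdata", "aa_templates.tsv",
                                        package = "flexsite"))
  lines <- character()
  serial <- 1
  fmt <- function(type, serial, name, res, chain, resno, x, y, z, el) {
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, substr(name, 1, 4), res, chain, resno, x, y, z, 1, 0, el)
  }
  for (ci in seq_along(chains)) {
    offset <- c(0, 20, 40)[ci]
    for (ri in 1:4) {
      res <- c("ALA", "LEU", "SER", "GLY")[ri]
      tt <- tmpl[tmpl$resname == res & tmpl$element != "H", ]
      if (ca_only) tt <- tt[tt$atom == "CA", ]
      for (i in seq_len(nrow(tt))) {
        lines <- c(lines, fmt("ATOM", serial, tt$atom[i], res, chains[ci], ri,
                              tt$x[i] + 4 * ri + offset, tt$y[i] + offset * 0.2,
                              tt$z[i], tt$element[i]))
        serial <- serial + 1
      }
    }
    lines <- c(lines, "TER")
  }
  if (with_water) {
    for (i in 1:3) {
      lines <- c(lines, fmt("HETATM", serial, "O", "HOH", "A", 100 + i,
                            10 + i, 10, 10, "O"))
      serial <- serial + 1
    }
  }
  if (!is.null(het)) lines <- c(lines, het$writer(serial, fmt))
  writeLines(c(lines, "END"), path)
  path
}

# het-group builders for preparation tests
het_ring <- function(resid, n_atoms, start_resno = 500, near = c(6, 0, 0),
                     chain = "A", element = "C") {
  list(writer = function(serial, fmt) {
    out <- character()
    for (i in seq_len(n_atoms)) {
      ang <- 2 * pi * i / n_atoms
      r_ring <- n_atoms * 1.5 / (2 * pi)
      out <- c(out, fmt("HETATM", serial + i - 1, paste0(element, i), resid,
                        chain, start_resno, near[1] + r_ring * cos(ang),
                        near[2] + r_ring * sin(ang),
                        near[3] + 0.2 * (i %% 3), element))
    }
    out
  })
}
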