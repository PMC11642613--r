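# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (full re-enumeration, O(n^2) loops,
# union-find) and share no code with the implementations they verify.

# ---- brute-force annulus pair correlation -------------------------------

oracle_pair_correlation <- function(cells, ref_type, target_type, radii,
                                    delta, norm_constant, edge_correction,
                                    width, height) {
  refs <- cells[cells$cell_type == ref_type, ]
  tars <- cells[cells$cell_type == target_type, ]
  dens <- nrow(tars) / (width * height)
  sapply(radii, function(r) {
    lo <- max(r - delta / 2, 0)
    hi <- r + delta / 2
    local_d <- numeric(nrow(refs))
    for (i in seq_len(nrow(refs))) {
      cnt <- 0
      for (j in seq_len(nrow(tars))) {
        if (ref_type == target_type) {
          # same subset in the same order: j == i is the cell itself
          if (j == i) next
        }
        d <- sqrt((refs$x[i] - tars$x[j])^2 + (refs$y[i] - tars$y[j])^2)
        if (d >= lo && d < hi) cnt <- cnt + 1
      }
      # areas come from the package's closed-form geometry (itself checked
      # against Monte Carlo integration in a separate test); the counting
      # and averaging logic here stays fully independent
      area <- if (edge_correction) {
        icsim::annulus_area_in_rect(refs$x[i], refs$y[i], lo, hi, width, height)
      } else {
        pi * (hi^2 - lo^2)
      }
      local_d[i] <- cnt / area
    }
    (mean(local_d) - dens) / norm_constant
  })
}

# Monte Carlo annulus-in-rectangle area (oracle for the closed form)
oracle_annulus_area <- function(x, y, lo, hi, width, height, n = 2e5) {
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n, lo^2, hi^2))
  px <- x + rr * cos(th)
  py <- y + rr * sin(th)
  mean(px >= 0 & px <= width & py >= 0 & py <= height) * pi * (hi^2 - lo^2)
}

# ---- union-find connected components ------------------------------------

oracle_components <- function(adjacent) {
  n <- nrow(adjacent)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && adjacent[i, j]) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical multiset signature of a clustering: sorted (size, touches) pairs
cluster_signature <- function(sizes, touches) {
  paste(sort(paste(sizes, touches, sep = "/")), collapse = ";")
}

# ---- naive kinetic Monte Carlo ------------------------------------------

# Full re-enumeration KMC for small lattices: every step rebuilds the whole
# event list from the state. Feedback is not modeled (use a dt_feedback
# longer than t_end and zero gains). Used to check that the incremental
# engine is distribution-identical.
oracle_kmc_final <- function(counts, params, t_end, cap,
                             contact = "moore8", hop = "vonneumann4") {
  nr <- dim(counts)[1]
  nc <- dim(counts)[2]
  M <- counts[, , 1]
  Tm <- counts[, , 2]
  E <- counts[, , 3]
  A <- counts[, , 4]
  occ <- function() M + Tm + E + A
  nb_offsets <- function(kind) {
    if (kind == "moore8") {
      expand.grid(dr = -1:1, dc = -1:1)
    } else {
      data.frame(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))
    }
  }
  cn <- nb_offsets(contact)
  hn <- nb_offsets(hop)
  hn <- hn[!(hn$dr == 0 & hn$dc == 0), ]
  nbsum <- function(m, offs) {
    out <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      for (r in 1:nr) {
        for (cc in 1:nc) {
          rr <- r + offs$dr[k]
          c2 <- cc + offs$dc[k]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
            out[r, cc] <- out[r, cc] + m[rr, c2]
          }
        }
      }
    }
    out
  }
  t <- 0
  repeat {
    Mnb <- nbsum(M, cn)
    Tnb <- nbsum(Tm, cn)
    events <- list()
    add <- function(rate, fn) {
      if (rate > 0) events[[length(events) + 1]] <<- list(rate = rate, fn = fn)
    }
    for (r in 1:nr) {
      for (cc in 1:nc) {
        r0 <- r
        c0 <- cc
        add(params$r_prolif_mel * M[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() place_daughter(r1, c1, "M")
        }))
        add(params$l * M[r0, c0] * Tnb[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() M[r1, c1] <<- M[r1, c1] - 1
        }))
        add(params$bC * Tm[r0, c0] * Mnb[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() {
            Tm[r1, c1] <<- Tm[r1, c1] - 1
            E[r1, c1] <<- E[r1, c1] + 1
          }
        }))
        add(params$bM * Tm[r0, c0] * A[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() {
            Tm[r1, c1] <<- Tm[r1, c1] - 1
            E[r1, c1] <<- E[r1, c1] + 1
          }
        }))
        add(params$r_prolif_T0 * Tm[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() place_daughter(r1, c1, "T")
        }))
        add(params$r_death_ex * E[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() E[r1, c1] <<- E[r1, c1] - 1
        }))
        add(params$r_hop_T * Tm[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() hop_one(r1, c1, "T")
        }))
        add(params$r_hop_T * E[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() hop_one(r1, c1, "E")
        }))
        add(params$r_hop_M * A[r0, c0], local({
          r1 <- r0; c1 <- c0
          function() hop_one(r1, c1, "A")
        }))
      }
    }
    add(params$r_recruit0, function() {
      i <- sample.int(nr * nc, 1)
      r1 <- (i - 1) %% nr + 1
      c1 <- (i - 1) %/% nr + 1
      o <- occ()
      if (o[r1, c1] < cap) Tm[r1, c1] <<- Tm[r1, c1] + 1
    })
    place_daughter <- function(r1, c1, what) {
      o <- occ()
      if (o[r1, c1] < cap) {
        tgt <- c(r1, c1)
      } else {
        opts <- NULL
        for (k in seq_len(nrow(hn))) {
          rr <- r1 + hn$dr[k]
          c2 <- c1 + hn$dc[k]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && o[rr, c2] < cap) {
            opts <- rbind(opts, c(rr, c2))
          }
        }
        if (is.null(opts)) return(invisible())
        tgt <- opts[sample.int(nrow(opts), 1), ]
      }
      if (what == "M") M[tgt[1], tgt[2]] <<- M[tgt[1], tgt[2]] + 1
      if (what == "T") Tm[tgt[1], tgt[2]] <<- Tm[tgt[1], tgt[2]] + 1
    }
    hop_one <- function(r1, c1, what) {
      k <- sample.int(nrow(hn), 1)
      rr <- r1 + hn$dr[k]
      c2 <- c1 + hn$dc[k]
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) return(invisible())
      if (occ()[rr, c2] >= cap) return(invisible())
      if (what == "T") {
        Tm[r1, c1] <<- Tm[r1, c1] - 1
        Tm[rr, c2] <<- Tm[rr, c2] + 1
      } else if (what == "E") {
        E[r1, c1] <<- E[r1, c1] - 1
        E[rr, c2] <<- E[rr, c2] + 1
      } else {
        A[r1, c1] <<- A[r1, c1] - 1
        A[rr, c2] <<- A[rr, c2] + 1
      }
    }
    rates <- vapply(events, function(e) e$rate, numeric(1))
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t > t_end) break
    ev <- events[[sample.int(length(events), 1, prob = rates)]]
    ev$fn()
  }
  c(melanoma = sum(M), t_active = sum(Tm), t_exhausted = sum(E), tam = sum(A))
}

# ---- small builders ------------------------------------------------------

csr_slide <- function(n_by_type, width = 1000, height = 1000, id = "s1") {
  do.call(rbind, lapply(names(n_by_type), function(tp) {
    n <- n_by_type[[tp]]
    tibble::tibble(
      slide_id = id, x = runif(n, 0, width), y = runif(n, 0, height),
      cell_type = tp
    )
  }))
}
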