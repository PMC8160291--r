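# Independent brute-force oracles for the texture families: plain nested
# loops over voxels, written directly from the matrix definitions, kept
# deliberately separate from the package's compiled accumulation path.

o_dims <- function(lev) dim(lev)

o_in <- function(d, x, y, z) x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
  z >= 1 && z <= d[3]

o_offsets26 <- function() {
  out <- NULL
  for (a in -1:1) for (b in -1:1) for (cc in -1:1)
    if (!(a == 0 && b == 0 && cc == 0)) out <- rbind(out, c(a, b, cc))
  out
}

# Symmetric co-occurrence probability table for one offset.
o_glcm_p <- function(lev, ng, off) {
  d <- o_dims(lev)
  M <- matrix(0, ng, ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
    if (!o_in(d, xx, yy, zz)) next
    lj <- lev[xx, yy, zz]
    if (lj == 0) next
    M[li, lj] <- M[li, lj] + 1
    M[lj, li] <- M[lj, li] + 1
  }
  M
}

o_glcm_feats <- function(P) {
  eps <- .Machine$double.eps
  ng <- nrow(P)
  f <- setNames(numeric(24),
                c("Autocorrelation", "JointAverage", "ClusterProminence",
                  "ClusterShade", "ClusterTendency", "Contrast",
                  "Correlation", "DifferenceAverage", "DifferenceEntropy",
                  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
                  "Imc2", "InverseVariance", "JointEnergy", "JointEntropy",
                  "MCC", "MaximumProbability", "SumAverage", "SumEntropy",
                  "SumSquares"))
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    cs <- i + j - mux - muy
    f["ClusterProminence"] <- f["ClusterProminence"] + cs^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + cs^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + cs^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + ((i - j) / ng)^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * p
  }
  f["JointAverage"] <- mux
  f["Correlation"] <- if (sx * sy == 0) 1 else
    (f["Autocorrelation"] - mux * muy) / (sx * sy)
  kd <- 0:(ng - 1)
  f["DifferenceAverage"] <- sum(kd * pdiff)
  f["DifferenceEntropy"] <- -sum(pdiff * log2(pdiff + eps))
  f["DifferenceVariance"] <- sum((kd - f["DifferenceAverage"])^2 * pdiff)
  hxy <- -sum(P * log2(P + eps))
  f["JointEntropy"] <- hxy
  hx <- -sum(px * log2(px + eps)); hy <- -sum(py * log2(py + eps))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j] + eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + eps)
  }
  f["Imc1"] <- if (max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  f["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  pres <- which(px > 0)
  f["MCC"] <- if (length(pres) <= 1) 1 else {
    Q <- matrix(0, length(pres), length(pres))
    for (a in seq_along(pres)) for (b in seq_along(pres)) {
      s <- 0
      for (k in pres)
        s <- s + P[pres[a], k] * P[pres[b], k] / (px[pres[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  f["MaximumProbability"] <- max(P)
  ks <- 2:(2 * ng)
  f["SumAverage"] <- sum(ks * psum[ks])
  f["SumEntropy"] <- -sum(psum[ks] * log2(psum[ks] + eps))
  f
}

# Average of GLCM features over the 13 unique directions with pairs.
o_glcm_features <- function(lev, ng) {
  offs <- o_offsets26()
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0); length(nz) > 0 && o[nz[1]] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  acc <- NULL; nv <- 0
  for (r in seq_len(nrow(offs))) {
    M <- o_glcm_p(lev, ng, offs[r, ])
    if (sum(M) == 0) next
    fe <- o_glcm_feats(M / sum(M))
    acc <- if (is.null(acc)) fe else acc + fe
    nv <- nv + 1
  }
  acc / nv
}

# Run-length matrix for one direction (rows = level, cols = run length).
o_glrlm <- function(lev, ng, off, maxlen) {
  d <- o_dims(lev)
  M <- matrix(0, ng, maxlen)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    px <- x - off[1]; py <- y - off[2]; pz <- z - off[3]
    if (o_in(d, px, py, pz) && lev[px, py, pz] == li) next
    len <- 1
    cx <- x + off[1]; cy <- y + off[2]; cz <- z + off[3]
    while (o_in(d, cx, cy, cz) && lev[cx, cy, cz] == li) {
      len <- len + 1
      cx <- cx + off[1]; cy <- cy + off[2]; cz <- cz + off[3]
    }
    M[li, len] <- M[li, len] + 1
  }
  M
}

o_glrlm_feats <- function(M, np) {
  eps <- .Machine$double.eps
  ng <- nrow(M); nl <- ncol(M)
  nr <- sum(M)
  f <- c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
         GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
         RunLengthNonUniformity = 0, RunLengthNonUniformityNormalized = 0,
         RunPercentage = nr / np, GrayLevelVariance = 0, RunVariance = 0,
         RunEntropy = 0, LowGrayLevelRunEmphasis = 0,
         HighGrayLevelRunEmphasis = 0, ShortRunLowGrayLevelEmphasis = 0,
         ShortRunHighGrayLevelEmphasis = 0, LongRunLowGrayLevelEmphasis = 0,
         LongRunHighGrayLevelEmphasis = 0)
  rg <- rowSums(M); rl <- colSums(M)
  f["ShortRunEmphasis"] <- sum(rl / (1:nl)^2) / nr
  f["LongRunEmphasis"] <- sum(rl * (1:nl)^2) / nr
  f["GrayLevelNonUniformity"] <- sum(rg^2) / nr
  f["GrayLevelNonUniformityNormalized"] <- sum(rg^2) / nr^2
  f["RunLengthNonUniformity"] <- sum(rl^2) / nr
  f["RunLengthNonUniformityNormalized"] <- sum(rl^2) / nr^2
  mug <- sum((1:ng) * rg / nr); mul <- sum((1:nl) * rl / nr)
  f["GrayLevelVariance"] <- sum((rg / nr) * ((1:ng) - mug)^2)
  f["RunVariance"] <- sum((rl / nr) * ((1:nl) - mul)^2)
  f["RunEntropy"] <- -sum((M / nr) * log2(M / nr + eps))
  f["LowGrayLevelRunEmphasis"] <- sum(rg / (1:ng)^2) / nr
  f["HighGrayLevelRunEmphasis"] <- sum(rg * (1:ng)^2) / nr
  for (g in 1:ng) for (l in 1:nl) {
    f["ShortRunLowGrayLevelEmphasis"] <-
      f["ShortRunLowGrayLevelEmphasis"] + M[g, l] / (g^2 * l^2)
    f["ShortRunHighGrayLevelEmphasis"] <-
      f["ShortRunHighGrayLevelEmphasis"] + M[g, l] * g^2 / l^2
    f["LongRunLowGrayLevelEmphasis"] <-
      f["LongRunLowGrayLevelEmphasis"] + M[g, l] * l^2 / g^2
    f["LongRunHighGrayLevelEmphasis"] <-
      f["LongRunHighGrayLevelEmphasis"] + M[g, l] * g^2 * l^2
  }
  f[c("ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")] <-
    f[c("ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
        "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")] / nr
  f
}

o_glrlm_features <- function(lev, ng) {
  offs <- o_offsets26()
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0); length(nz) > 0 && o[nz[1]] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  np <- sum(lev > 0)
  maxlen <- max(o_dims(lev))
  acc <- NULL
  for (r in seq_len(nrow(offs))) {
    fe <- o_glrlm_feats(o_glrlm(lev, ng, offs[r, ], maxlen), np)
    acc <- if (is.null(acc)) fe else acc + fe
  }
  acc / nrow(offs)
}

# Zones by breadth-first search over equal-level 26-neighbours.
o_zones <- function(lev) {
  d <- o_dims(lev)
  seen <- array(FALSE, dim = d)
  offs <- o_offsets26()
  zg <- integer(0); zs <- integer(0)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    val <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nx <- cur[1] + offs[r, 1]; ny <- cur[2] + offs[r, 2]
        nz2 <- cur[3] + offs[r, 3]
        if (o_in(d, nx, ny, nz2) && !seen[nx, ny, nz2] &&
            lev[nx, ny, nz2] == val) {
          seen[nx, ny, nz2] <- TRUE
          queue[[length(queue) + 1]] <- c(nx, ny, nz2)
        }
      }
    }
    zg <- c(zg, val); zs <- c(zs, size)
  }
  list(g = zg, s = zs)
}

o_glszm_features <- function(lev, ng) {
  eps <- .Machine$double.eps
  zz <- o_zones(lev)
  g <- zz$g; s <- zz$s
  nz <- length(g); np <- sum(lev > 0)
  ngc <- tabulate(g, nbins = ng)
  nsc <- tabulate(s)
  mug <- sum((1:ng) * ngc / nz)
  mus <- sum(s) / nz
  pz <- as.numeric(table(paste(g, s))) / nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(ngc^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ngc^2) / nz^2,
    SizeZoneNonUniformity = sum(nsc^2) / nz,
    SizeZoneNonUniformityNormalized = sum(nsc^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((ngc / nz) * ((1:ng) - mug)^2),
    ZoneVariance = mean((s - mus)^2),
    ZoneEntropy = -sum(pz * log2(pz + eps)),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (g^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LargeAreaHighGrayLevelEmphasis = mean(g^2 * s^2))
}

o_ngtdm_features <- function(lev, ng) {
  d <- o_dims(lev)
  offs <- o_offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    vals <- c()
    for (r in seq_len(nrow(offs))) {
      nx <- x + offs[r, 1]; ny <- y + offs[r, 2]; nz2 <- z + offs[r, 3]
      if (o_in(d, nx, ny, nz2) && lev[nx, ny, nz2] > 0)
        vals <- c(vals, lev[nx, ny, nz2])
    }
    n_i[li] <- n_i[li] + 1
    if (length(vals) > 0) s_i[li] <- s_i[li] + abs(li - mean(vals))
  }
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  pres <- which(p_i > 0)
  ngp <- length(pres)
  coars <- if (sum(p_i * s_i) == 0) 1e6 else 1 / sum(p_i * s_i)
  contr <- 0; busy_den <- 0; compl <- 0; stren <- 0
  if (ngp > 1) {
    for (a in pres) for (b in pres) {
      contr <- contr + p_i[a] * p_i[b] * (a - b)^2
      busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
      compl <- compl + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
      stren <- stren + (p_i[a] + p_i[b]) * (a - b)^2
    }
    contr <- contr / (ngp * (ngp - 1)) * sum(s_i) / nvp
    compl <- compl / nvp
    stren <- if (sum(s_i) == 0) 0 else stren / sum(s_i)
  }
  busy <- if (ngp > 1 && busy_den > 0) sum(p_i * s_i) / busy_den else 0
  c(Coarseness = coars, Contrast = contr, Busyness = busy,
    Complexity = compl, Strength = stren)
}

o_gldm_features <- function(lev, ng, alpha = 0) {
  eps <- .Machine$double.eps
  d <- o_dims(lev)
  offs <- o_offsets26()
  M <- matrix(0, ng, 27)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 0
    for (r in seq_len(nrow(offs))) {
      nx <- x + offs[r, 1]; ny <- y + offs[r, 2]; nz2 <- z + offs[r, 3]
      if (o_in(d, nx, ny, nz2) && lev[nx, ny, nz2] > 0 &&
          abs(lev[nx, ny, nz2] - li) <= alpha)
        dep <- dep + 1
    }
    M[li, dep + 1] <- M[li, dep + 1] + 1
  }
  nd <- ncol(M)
  nz <- sum(M)
  dg <- rowSums(M); dd <- colSums(M)
  mug <- sum((1:ng) * dg / nz); mud <- sum((1:nd) * dd / nz)
  sdlgle <- sdhgle <- ldlgle <- ldhgle <- 0
  for (g in 1:ng) for (j in 1:nd) {
    sdlgle <- sdlgle + M[g, j] / (g^2 * j^2)
    sdhgle <- sdhgle + M[g, j] * g^2 / j^2
    ldlgle <- ldlgle + M[g, j] * j^2 / g^2
    ldhgle <- ldhgle + M[g, j] * g^2 * j^2
  }
  c(SmallDependenceEmphasis = sum(dd / (1:nd)^2) / nz,
    LargeDependenceEmphasis = sum(dd * (1:nd)^2) / nz,
    GrayLevelNonUniformity = sum(dg^2) / nz,
    DependenceNonUniformity = sum(dd^2) / nz,
    DependenceNonUniformityNormalized = sum(dd^2) / nz^2,
    GrayLevelVariance = sum((dg / nz) * ((1:ng) - mug)^2),
    DependenceVariance = sum((dd / nz) * ((1:nd) - mud)^2),
    DependenceEntropy = -sum((M / nz) * log2(M / nz + eps)),
    LowGrayLevelEmphasis = sum(dg / (1:ng)^2) / nz,
    HighGrayLevelEmphasis = sum(dg * (1:ng)^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sdlgle / nz,
    SmallDependenceHighGrayLevelEmphasis = sdhgle / nz,
    LargeDependenceLowGrayLevelEmphasis = ldlgle / nz,
    LargeDependenceHighGrayLevelEmphasis = ldhgle / nz)
}
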