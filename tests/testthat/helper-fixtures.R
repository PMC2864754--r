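# Shared fixtures and independent oracles, built in code at test time.

# full 2 x 5 x n_rep design sheet; drop_degraded removes treated day-2
# replicate n_rep (the 39-array layout)
make_design <- function(n_rep = 4, drop_degraded = FALSE) {
  s <- expand.grid(replicate = seq_len(n_rep),
                   treatment = c("control", "treated"),
                   day = 1:5, stringsAsFactors = FALSE)
  s <- s[, c("day", "treatment", "replicate")]
  if (drop_degraded) {
    s <- s[!(s$day == 2 & s$treatment == "treated" & s$replicate == n_rep), ]
  }
  s$sample_id <- sprintf("d%d_%s_r%d", s$day,
                         substr(s$treatment, 1, 1), s$replicate)
  rownames(s) <- NULL
  s
}

make_dataset <- function(values, sheet) {
  expr_dataset(values, sheet)
}

# igraph from an edge data.frame with fbs
toy_graph <- function(from, to, fbs = 5) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, fbs = fbs, relation = "pp"),
    directed = FALSE)
}

# independent oracle: balanced two-way ANOVA sums of squares from cell
# means (classical textbook decomposition; valid for balanced designs,
# where Type I = Type II)
oracle_twoway_ss <- function(y, day, trt) {
  day <- factor(day); trt <- factor(trt)
  gm <- mean(y)
  ma <- tapply(y, day, mean)
  mb <- tapply(y, trt, mean)
  mab <- tapply(y, list(day, trt), mean)
  na <- tapply(y, day, length)
  nb <- tapply(y, trt, length)
  nab <- tapply(y, list(day, trt), length)
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  ss_ab <- sum(nab * (sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  ss_res <- sum((y - mab[cbind(day, trt)])^2)
  list(day = ss_a, trt = ss_b, int = ss_ab, res = ss_res,
       tot = sum((y - gm)^2))
}

# independent oracle: balanced three-way ANOVA SS from cell means
oracle_threeway_ss <- function(y, f1, f2, f3) {
  f1 <- factor(f1); f2 <- factor(f2); f3 <- factor(f3)
  gm <- mean(y)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m3 <- tapply(y, f3, mean)
  m12 <- tapply(y, list(f1, f2), mean)
  m13 <- tapply(y, list(f1, f3), mean)
  m23 <- tapply(y, list(f2, f3), mean)
  m123 <- tapply(y, list(f1, f2, f3), mean)
  n <- length(y)
  r <- n / (nlevels(f1) * nlevels(f2) * nlevels(f3))
  a <- nlevels(f1); b <- nlevels(f2); cc <- nlevels(f3)
  ss1 <- r * b * cc * sum((m1 - gm)^2)
  ss2 <- r * a * cc * sum((m2 - gm)^2)
  ss3 <- r * a * b * sum((m3 - gm)^2)
  ss12 <- r * cc * sum((m12 - outer(m1, rep(1, b)) -
                          outer(rep(1, a), m2) + gm)^2)
  ss13 <- r * b * sum((m13 - outer(m1, rep(1, cc)) -
                         outer(rep(1, a), m3) + gm)^2)
  ss23 <- r * a * sum((m23 - outer(m2, rep(1, cc)) -
                         outer(rep(1, b), m3) + gm)^2)
  int3 <- m123
  for (i in seq_len(a)) for (j in seq_len(b)) for (k in seq_len(cc)) {
    int3[i, j, k] <- m123[i, j, k] - m12[i, j] - m13[i, k] - m23[j, k] +
      m1[i] + m2[j] + m3[k] - gm
  }
  ss123 <- r * sum(int3^2)
  res <- sum((y - m123[cbind(f1, f2, f3)])^2)
  list(ss1 = ss1, ss2 = ss2, ss3 = ss3, ss12 = ss12, ss13 = ss13,
       ss23 = ss23, ss123 = ss123, res = res, tot = sum((y - gm)^2))
}

# independent oracle: exact hypergeometric upper tail by enumeration
brute_hyper_tail <- function(M, K, m, k) {
  j <- k:min(K, m)
  sum(choose(K, j) * choose(M - K, m - j)) / choose(M, m)
}

# edge keys for comparing link sets
ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# scale-free background with an attached clique of named genes (dense
# planted module structure)
embed_cliques <- function(n_background, cliques, seed) {
  bb <- generate_backbone(n_background, m = 2, seed = seed)
  ed <- igraph::as_data_frame(bb, "edges")[, c("from", "to")]
  for (i in seq_along(cliques)) {
    pairs <- t(combn(cliques[[i]], 2))
    ed <- rbind(ed, data.frame(from = pairs[, 1], to = pairs[, 2]),
                data.frame(from = cliques[[i]][1],
                           to = igraph::V(bb)$name[i]))
  }
  ed$fbs <- 8; ed$relation <- "pp"
  igraph::graph_from_data_frame(ed, directed = FALSE)
}

# connected hub-neighbourhood gene set for planting
pick_set <- function(bb, hub_rank, n, avoid = character(0)) {
  deg <- igraph::degree(bb)
  hubs <- names(sort(deg, decreasing = TRUE))
  h <- setdiff(hubs, avoid)[hub_rank]
  nb <- setdiff(names(igraph::neighbors(bb, h)), c(h, avoid))
  c(h, head(nb, n - 1))
}

# backbone carrying k disjoint planted flows (n_links parallel edges
# between each flow's source and target GO categories; no noise links
# among annotated genes) plus background edges among unannotated genes
flow_fixture <- function(k = 5, n_links = 3, n_background = 30, seed = 1) {
  src <- lapply(seq_len(k), function(i) sprintf("f%dsrc%02d", i, seq_len(n_links)))
  tgt <- lapply(seq_len(k), function(i) sprintf("f%dtgt%02d", i, seq_len(n_links)))
  ed <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(from = src[[i]], to = tgt[[i]])
  }))
  bg <- sprintf("bg%03d", seq_len(n_background))
  set.seed(seed)
  ed <- rbind(ed, data.frame(from = sample(bg, n_background, TRUE),
                             to = sample(bg, n_background, TRUE)))
  ed <- ed[ed$from != ed$to, ]
  g <- igraph::graph_from_data_frame(
    cbind(ed, fbs = 8, relation = "pp"), directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(fbs = "max",
                                                 relation = "first"))
  gene2go <- list()
  for (i in seq_len(k)) {
    for (g2 in src[[i]]) gene2go[[g2]] <- sprintf("GO:SRC%d", i)
    for (g2 in tgt[[i]]) gene2go[[g2]] <- sprintf("GO:TGT%d", i)
  }
  flows <- data.frame(go_source = sprintf("GO:SRC%d", seq_len(k)),
                      day_a = 1,
                      go_target = sprintf("GO:TGT%d", seq_len(k)),
                      n_links = n_links)
  list(graph = g, gene2go = gene2go, flows = flows,
       src = src, tgt = tgt)
}

# minimal de_calls object with given first-DE days
make_de_calls <- function(genes, first) {
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  out$de_days <- lapply(first, function(d) if (is.na(d)) integer(0) else d)
  out$first_de_day <- first
  out$developmental <- FALSE
  class(out) <- c("de_calls", class(out))
  out
}

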