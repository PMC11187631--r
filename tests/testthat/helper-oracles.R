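# Brute-force Shapley oracle over all feature subsets, with the
# cover-weighted tree-conditional value function computed directly on the
# dumped tree structure.
treeValue <- function(dt, x, S) {
  total <- 0
  for (tr in unique(dt$Tree)) {
    nodes <- dt[dt$Tree == tr, ]
    rec <- function(id) {
      nd <- nodes[nodes$ID == id, ]
      if (nd$Feature == "Leaf") return(nd$Gain)  # leaf value
      f <- as.integer(nd$Feature) + 1L
      if (f %in% S) {
        nxt <- if (x[f] < nd$Split) nd$Yes else nd$No
        return(rec(nxt))
      }
      cy <- nodes$Cover[nodes$ID == nd$Yes]
      cn <- nodes$Cover[nodes$ID == nd$No]
      (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
    }
    total <- total + rec(nodes$ID[1])
  }
  total
}

oracleShapley <- function(dt, x, nfeat) {
  phi <- numeric(nfeat)
  subsets <- lapply(0:(2^nfeat - 1), function(m) which(bitwAnd(m,
    2^(seq_len(nfeat) - 1)) > 0))
  vals <- vapply(subsets, function(S) treeValue(dt, x, S), numeric(1))
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  lookup <- function(S) vals[match(sum(2^(S - 1)), key)]
  for (j in seq_len(nfeat)) {
    for (idx in seq_along(subsets)) {
      S <- subsets[[idx]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(nfeat - length(S) - 1) /
        factorial(nfeat)
      phi[j] <- phi[j] + w * (lookup(c(S, j)) - vals[idx])
    }
  }
  phi
}

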