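# Shared fixtures, built once per test run.

# small synthetic universe reused by forest/evaluation tests
smallCfg <- simConfig(nGenes = 400L, nTsg = 16L, nOg = 16L, seed = 7L)
smallUniverse <- generateUniverse(smallCfg)
smallPrep <- prepareFeatures(smallUniverse$features)
smallTraining <- data.frame(
  gene_id = smallUniverse$truth@geneId,
  class = as.character(smallUniverse$truth@trueClass))

# LabelSet builder from a named tier character vector
makeLabelSet <- function(tierVec, provenance = NULL) {
  tier <- factor(tierVec, levels = c("high_TSG", "high_OG", "medium", "low",
                                     "other", "background"))
  names(tier) <- names(tierVec)
  if (is.null(provenance)) {
    high <- names(tier)[tier %in% c("high_TSG", "high_OG")]
    provenance <- setNames(rep("fixture", length(high)), high)
  }
  new("LabelSet", tier = tier, provenance = provenance)
}

# FeatureTable builder
makeFeatureTable <- function(df, types = NULL) {
  if (is.null(types))
    types <- setNames(rep("continuous", ncol(df)), names(df))
  new("FeatureTable", data = df, featureType = types)
}

# minimal SourceMembership builder
makeMembership <- function(member, role = NULL, categories = NULL) {
  if (is.null(role)) {
    role <- matrix(NA_character_, nrow(member), ncol(member),
                   dimnames = dimnames(member))
    role[member] <- "unknown"
  }
  if (is.null(categories)) categories <- rep("db", ncol(member))
  new("SourceMembership", membership = member, role = role,
      sourceInfo = data.frame(name = colnames(member),
                              category = categories))
}

# brute-force betweenness: enumerate all shortest paths between every pair
bruteBetweenness <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  allPaths <- function(from, to) {
    # enumerate simple paths, keep the shortest ones
    best <- list(); bestLen <- Inf
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        if (length(path) < bestLen) { best <<- list(path); bestLen <<- length(path) }
        else if (length(path) == bestLen) best[[length(best) + 1]] <<- path
        return()
      }
      if (length(path) >= bestLen) return()
      for (nb in adj[[last]]) if (!(nb %in% path)) walk(c(path, nb))
    }
    walk(from)
    best
  }
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- allPaths(nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# brute-force hypergeometric upper tail by subset enumeration
bruteHyperUpper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)  # items 1..K are the successes
  mean(hits >= k)
}
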