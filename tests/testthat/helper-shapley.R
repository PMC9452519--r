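# Brute-force Shapley oracle for small tree ensembles, independent of the
# package's attribution path. The value function v(S, x) marginalizes
# features outside S by cover-weighted averaging over both children at each
# split, matching the tree-path-dependent expectation TreeSHAP uses; phi_i
# is then the exact Shapley average over all subsets (feasible for <= 8
# features).

# xgboost compares feature values as float32; emulate that rounding so
# data points lying exactly on a learned split route the same way here.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric", size = 4)
}

tree_value <- function(tree, x, in_coalition) {
  walk <- function(id) {
    row <- tree[tree$ID == id, ]
    if (row$Feature == "Leaf") return(row$Gain)
    f <- row$Feature
    if (in_coalition[[f]]) {
      xv <- x[[f]]
      nxt <- if (is.na(xv)) row$Missing
             else if (as_float32(xv) < as_float32(row$Split)) row$Yes
             else row$No
      return(walk(nxt))
    }
    cy <- tree[tree$ID == row$Yes, ]$Cover
    cn <- tree[tree$ID == row$No, ]$Cover
    (cy * walk(row$Yes) + cn * walk(row$No)) / (cy + cn)
  }
  walk(tree$ID[1])
}

# Margin contribution of one class: sum of that class's trees under
# coalition S (base score is constant in S and cancels in Shapley
# differences).
ensemble_value <- function(trees_for_class, x, in_coalition) {
  sum(vapply(trees_for_class, tree_value, 0, x = x,
             in_coalition = in_coalition))
}

brute_force_shapley <- function(model, x, num_class) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  features <- names(x)
  m <- length(features)
  stopifnot(m <= 8)
  trees <- split(dt, dt$Tree)
  tree_ids <- as.integer(names(trees))
  phi <- matrix(0, num_class, m, dimnames = list(NULL, features))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  names(subsets) <- features
  for (cl in seq_len(num_class) - 1L) {
    cls_trees <- trees[tree_ids %% num_class == cl]
    # cache v(S) for every subset once
    v <- apply(subsets, 1, function(s) {
      ensemble_value(cls_trees, x, as.list(s))
    })
    key <- apply(subsets, 1, function(s) paste(as.integer(s), collapse = ""))
    v_of <- setNames(v, key)
    for (i in seq_len(m)) {
      without_i <- subsets[!subsets[[i]], , drop = FALSE]
      for (r in seq_len(nrow(without_i))) {
        s <- unlist(without_i[r, ])
        size <- sum(s)
        w <- factorial(size) * factorial(m - size - 1) / factorial(m)
        s_with <- s; s_with[i] <- TRUE
        k0 <- paste(as.integer(s), collapse = "")
        k1 <- paste(as.integer(s_with), collapse = "")
        phi[cl + 1L, i] <- phi[cl + 1L, i] + w * (v_of[[k1]] - v_of[[k0]])
      }
    }
  }
  phi
}
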