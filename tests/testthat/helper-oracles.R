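# independent Spearman oracle: explicit mid-ranks, then the Pearson formula
# written out by hand (no call to cor())
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  n <- length(rx)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force three-way set split used as oracle for set comparisons
setsplit_oracle <- function(items1, items2) {
  items1 <- unique(items1); items2 <- unique(items2)
  all_items <- union(items1, items2)
  shared <- all_items[vapply(all_items, function(i) i %in% items1 && i %in% items2, logical(1))]
  u1 <- all_items[vapply(all_items, function(i) i %in% items1 && !(i %in% items2), logical(1))]
  u2 <- all_items[vapply(all_items, function(i) !(i %in% items1) && i %in% items2, logical(1))]
  list(shared = sort(shared), unique1 = sort(u1), unique2 = sort(u2))
}

expect_set_comparison_valid <- function(cmp) {
  expect_length(intersect(cmp$shared, cmp$unique1), 0)
  expect_length(intersect(cmp$shared, cmp$unique2), 0)
  expect_length(intersect(cmp$unique1, cmp$unique2), 0)
}
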