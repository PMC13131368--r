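#!/usr/bin/env Rscript
# Dataset-handling arithmetic: the 10%/90% train-vs-predict holdout on
# the study's 6,702 filtered images, and an animal-grouped 70/15/15
# train/val/test split on a simulated image inventory (67 calves with
# uneven image counts) showing that no animal ever spans two subsets.

library(calfface)

dir.create("results", showWarnings = FALSE)

h <- holdout_count(6702, 0.10)
cat(sprintf(
  "holdout: %d images -> %d training (10%%), %d retained for prediction\n",
  6702, h[["train"]], h[["predict"]]
))

set.seed(301)
n_images <- pmax(1L, rpois(67, 100)) # uneven images per calf
units <- data.frame(
  image_id = sprintf("img%05d", seq_len(sum(n_images))),
  animal_id = rep(sprintf("calf%02d", 1:67), times = n_images)
)
sp <- group_split(units, c(train = 0.70, val = 0.15, test = 0.15), seed = 302)
counts <- table(sp$subset)
cat("grouped split image counts (targets 70/15/15):\n")
print(round(100 * counts / sum(counts), 1))
leak <- tapply(sp$subset, sp$animal_id, function(s) length(unique(s)))
cat("animals spanning more than one subset:", sum(leak > 1), "\n")
# persist the animal-level assignment (one row per calf, not per image)
per_animal <- unique(sp[, c("animal_id", "subset")])
per_animal$n_images <- as.integer(table(sp$animal_id)[per_animal$animal_id])
utils::write.csv(per_animal[order(per_animal$animal_id), ],
  file.path("results", "split.csv"),
  row.names = FALSE
)
cat("wrote results/split.csv (animal-level assignment)\n")
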