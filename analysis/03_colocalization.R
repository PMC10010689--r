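#!/usr/bin/env Rscript
# Object-based co-localisation on ten planted channel pairs (one per
# simulated animal): percentage of channel-A objects whose centroid lies in
# a channel-B object, averaged across images.

library(meisoquant)

out <- "results/coloc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

planted <- 0.3
res <- lapply(1:10, function(i) {
  pair <- generate_coloc_pair(10, 12, planted, seed = 200L + i)
  centroid_in_mask_pct(pair$labels_A, pair$labels_B)
})
s <- coloc_summary(res)
write.csv(cbind(image = seq_along(res), s$per_image),
          file.path(out, "per_image.csv"), row.names = FALSE)
write.csv(data.frame(direction = c("A_in_B", "B_in_A"),
                     mean_pct = c(s$A_in_B$mean, s$B_in_A$mean),
                     sd_pct = c(s$A_in_B$sd, s$B_in_A$sd),
                     n_images = c(s$A_in_B$n_images, s$B_in_A$n_images)),
          file.path(out, "summary.csv"), row.names = FALSE)

cat(sprintf("planted fraction %.0f%%: study mean A-in-B %.1f%% +/- %.1f (n = %d images)\n",
            100 * planted, s$A_in_B$mean, s$A_in_B$sd, s$A_in_B$n_images))
cat(sprintf("reverse direction B-in-A %.1f%% (not planted, geometry-driven)\n",
            s$B_in_A$mean))
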