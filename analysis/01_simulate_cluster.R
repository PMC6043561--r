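#!/usr/bin/env Rscript
# Simulate the reduced-grid scenario once and record what happens.
#
# A senescent cell (bulged core + 12 thin body domains) sits on the
# substrate of a 64 x 64 x 20 um lattice with 6 tumor cells seeded
# outside its body. The core secretes a chemoattractant; tumor cells
# divide with period 5000 +/- 1000 s, transiently losing substrate
# adhesion while mitotically rounded. We run the published duration of
# 8800 s (1 MCS = 1 s) and ask whether newly divided cells climb the
# body and cluster on the core, as in the live-imaging observation.
library(sencluster)

out <- "results/cluster_run"
cfg <- reduced_config(run = list(n_mcs = 8800L, seed = 1L,
                                 track_every = 50L, snapshot_every = 2200L))
cat("running reduced scenario (8800 MCS, seed 1)...\n")
res <- run_simulation(cfg, out_dir = out)

cat(sprintf("\ndivision events: %d\n", nrow(res$events)))
m <- res$metrics
cat(sprintf("cluster metrics at t = %d s:\n", res$state$t))
cat(sprintf("  tumor cells on the core:  %d\n", m$n_cells_on_core))
cat(sprintf("  tallest tumor stack:      %g um\n", m$max_stack_height))
cat(sprintf("  cluster formed (>= 2):    %s\n", m$cluster_formed))

# where did the tumor cells end up?
cells <- res$state$cells
tum <- cells[cells$type == 3 & cells$vol > 0, ]
z_of <- function(id) sencluster:::periodic_centroid(res$state$grid, id)[3]
z <- vapply(tum$id, z_of, numeric(1))
if (any(tum$gen == 0))
  cat(sprintf("\nmean centroid height, never divided: %.1f um (n=%d)\n",
              mean(z[tum$gen == 0]), sum(tum$gen == 0)))
cat(sprintf("\ncentroid heights (um) by cell: %s\n",
            paste(sprintf("%.1f", sort(z)), collapse = " ")))
cat(sprintf("cells above the body top sit on the core; the rest remain on\n"))
cat(sprintf("the substrate at ~2.7 um - the height a cell reaches only by\n"))
cat(sprintf("climbing during its mitotic-rounding window.\n"))
cat("outputs (tracks, events, energy, metrics, config) in ", out, "\n")
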