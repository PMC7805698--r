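# latchmem

Simulation library for a three-network cognitive memory model: a
content-addressable **identification (WHAT)** attractor network with
Hebbian storage and short-term synaptic depression, a winner-take-all
**localization (WHERE)** network over orthogonal place codes, and a
**prefrontal-style working memory** that recruits a node for every novel
object–place conjunction and biases recall toward recent experience.
Delayed predictive associations between attractor states let the system
replay experienced episodes when decoupled from input, and a comparator
turns expectation mismatches into total and feature-specific surprise
signals.

The package is for computational cognitive scientists and cognitive
robotics researchers who want a small, fully deterministic-under-seed
sandbox in which classic memory phenomena emerge from one architecture:
pattern completion, object permanence (place and object recall), the
A-not-B error and its disappearance with working-memory maturity,
delayed matching to sample, semantic mind-wandering, episodic replay
with reverie blending, and vicarious trial and error.

## The model in brief

Stimuli are bipolar patterns $\xi \in \{-1,+1\}^N$. The WHAT network
stores them with the Hebbian rule
$W_{ij} = \frac{1}{N}\sum_\mu \xi_i^\mu \xi_j^\mu$ ($W_{ii}=0$) and
evolves by asynchronous updates of
$$h_i = \sum_j W_{ij}\, r_j s_j \;+\; g_{bu}\, e_i \;+\; g_{td}\, t_i,$$
where $r_j \in [0,1]$ is a Tsodyks-style depression resource
($r_j \mathrel{+}= (1-r_j)/\tau_{rec} - U\,r_j\,[s_j{=}+1]$), $e$ is the
stimulus and $t$ the top-down drive from working memory, bindings, or
the predictive map. Units are $\mathrm{sign}$ units in the
deterministic limit or logistic-stochastic at finite gain $\beta$ — the
arousal metaparameter that controls the randomness of transitions
between attractors. The energy
$E = -\tfrac12 \sum_{i \ne j} W_{ij} s_i s_j$ decreases during recall.
Working-memory nodes snapshot the joint WHAT×WHERE state; selection
weighs *activity × similarity*, so a partial cue recalls the most
recent matching state. The methods vignette
(`vignettes/latchmem-model.Rmd`) derives the details and documents
every default.

## Worked example

```r
library(latchmem)

tri <- make_semantic_triplet()            # objects X, Y, Z (X,Y and Y,Z share features)
places <- place_codes(c("A", "B", "C"), 8)
sys <- memory_system(tri, places)

sys <- perceive(sys, tri[[1]], "A")       # see X at A
sys <- perceive(sys, tri[[2]], "B")       # see Y at B
sys <- perceive(sys, tri[[3]], "C")       # see Z at C

recall_place(sys, tri[[1]])$place         # where was X?
#> [1] "A"
recall_object(sys, "B")$object            # what was at B?
#> [1] "Y"
recall_place(sys, shared_cue(tri[[1]], tri[[2]]))$place
#> [1] "B"
```

The last call cues the system with only the features X and Y share; the
answer is `"B"` because Y was seen more recently — working memory breaks
the tie, and the WHAT network completes the full Y pattern while doing
so. The same machinery run as a packaged task:

```r
res <- run_task(task_config("a_not_b", seed = 1))
res
#> <task_result 'a_not_b': 2/2 checks passed>
#>   [ok] low_gain_perseverates
#>   [ok] high_gain_updates
res$summary$answers
#>   0  20
#> "A" "B"
```

After four presentations of X at A and one at B, the model asked "where
is X?" answers `A` with the working-memory gain at 0 (the perseverative
A-not-B error of an immature prefrontal system) and `B` at gain 20.

Eight seeded task runners cover the full simulation suite —
`pattern_completion`, `place_recall`, `object_recall`, `a_not_b`,
`dmts`, `semantic_wandering`, `episodic_recall`, `vte` — each returning
a `task_result` with re-checkable verdicts, traces and summary
counters. A thin command-line front end wraps them:

```sh
Rscript inst/cli/latchmem.R run a_not_b --seed 1 --out out/
Rscript inst/cli/latchmem.R sweep vte --seeds 1,2,3 --out out/vte
Rscript inst/cli/latchmem.R report out/vte/seed_1
```

Each run writes its traces as TSV plus a `manifest.json` sufficient to
re-run the task byte-identically.

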