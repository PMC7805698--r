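---
title: "The latchmem memory model: dynamics, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The latchmem memory model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latchmem)
```

## The model

latchmem simulates a three-network cognitive memory architecture:

* an **identification (WHAT) network** — a fully connected attractor
  network over bipolar feature units that stores stimulus patterns and
  recalls complete patterns from partial cues;
* a **localization (WHERE) network** — orthogonal one-hot place codes
  under a winner-take-all rule, so at most one place is represented at a
  time;
* a **working memory** — a pool of nodes recruited on demand, one per
  novel object–place conjunction, whose activity decays with every
  subsequent recruitment and which can excite/inhibit the two cortical
  networks top-down.

Hetero-associative **bindings** link objects to places in both
directions, and a **predictive map** learns delayed transitions between
attractor states, which lets the system replay experienced episodes when
it runs free of input. A **comparator** measures the mismatch between
the sensory input and the current attractor state, producing a total and
a per-feature surprise signal; a large enough mismatch resets the memory
state so a novel stimulus can be coded quickly.

### WHAT-network dynamics

Patterns are bipolar vectors $\xi \in \{-1,+1\}^N$ with labels. Storage
is Hebbian,
$$W_{ij} = \frac{1}{N}\sum_\mu \xi_i^\mu \xi_j^\mu \quad (i \ne j,\; W_{ii}=0),$$
with a variance-normalized covariance variant (`rule = "covariance"`)
for strongly correlated sets. The net input combines depressed
recurrence with bottom-up and top-down drive:
$$h_i = \sum_j W_{ij}\, r_j s_j + g_{bu}\,e_i + g_{td}\,t_i .$$

Units update asynchronously. In the deterministic limit
($\beta=\infty$) a unit takes $s_i \leftarrow \operatorname{sign}(h_i + \epsilon_i)$,
with $\operatorname{sign}(0)$ keeping the previous activation; at finite
gain the unit is stochastic,
$P(s_i = +1) = \operatorname{logistic}(2\beta (h_i+\epsilon_i))$, with
$\epsilon_i \sim N(0, \sigma^2)$. The gain $\beta$ is the arousal
metaparameter: it controls the randomness of state transitions without
changing the noise amplitude, the role attributed to the locus
coeruleus. Energy $E = -\tfrac12 \sum_{i\ne j} W_{ij} s_i s_j$ is a
recall diagnostic; with deterministic asynchronous updates, frozen
resources and no drive it is non-increasing at every update, which the
test suite asserts over 100 random starts.

### Synaptic depression

Each unit carries a presynaptic resource $r_j \in [0,1]$:
$$r_j \leftarrow r_j + \frac{1-r_j}{\tau_{rec}} - U\, r_j\, [s_j = +1],$$
clipped to $[0,1]$. A unit held active settles at
$r^* = (1/\tau_{rec})/(1/\tau_{rec} + U)$. Depression weakens the
attractor currently occupied and is what allows the state to wander.

One consequence of this coding deserves emphasis, because it shaped the
study conditions. A stored pattern's *inactive* units (the $-1$ rim)
never deplete, and their intact contribution alone keeps every active
unit's field positive for any $r \ge 0$. **Under fully deterministic
sign dynamics, depression alone can therefore never push the state out
of an attractor.** The leave-and-return regime ("the state wanders out
and falls back") is consequently run at zero input noise but *finite
gain* ($\sigma = 0$, $\beta = 3$): stochastic units make escapes
possible exactly where depression has weakened the field, which is the
gain-modulation account of arousal. This is a deliberate design choice,
not a numerical accident, and it is the package's reading of how a
bipolar implementation realizes depression-driven wandering.

### Settling, events and recall queries

`settle()` runs deterministic sweeps in fixed unit order until no unit
changes; depression is frozen during settling so convergence is well
defined (resources advance only in free-running mode). Attractor events
are detected at overlap $\ge 0.9$ sustained for $\ge 3$ steps, with ties
to the first stored pattern; both thresholds are shared between
`nearest_attractor()` and `event_log()`.

Recall queries (`recall_place()`, `recall_object()`) settle **from the
empty memory state** (activations cleared, resources kept). This
matches the picture of recall trajectories radiating from the empty
central state, and it makes query answers a function of cue + memory
rather than of whatever state the system lingered in. Queries never
learn: bindings and working memory are updated only at perception
events, which prevents self-reinforcing hallucinated bindings.

Binding readout uses the active place's column of the binding matrix
(equivalently $B\,\cdot$ the rectified place code). Reading out with
the raw $\pm1$ one-hot would inject $-\eta \times$ (every other bound
object) from the $-1$ entries — crosstalk with no biological analogue
here.

### Working memory

Nodes snapshot the joint WHAT$\times$WHERE state at recruitment and are
immutable afterwards. A new perception either re-activates a matching
node (joint similarity $\ge 0.95$) or recruits a fresh one; in both
cases all other nodes decay by $\lambda = 0.9$. Decay is event-driven
(per recruitment), not per time step: it makes the recency gradient
exact ($\lambda^k$ for the $k$-th most recent item) and order-preserving
regardless of how long a trial takes. Selection scores a node by
**activity $\times$ similarity**, similarity computed only over the
cue's non-neutral components; the product form guarantees that both
recency and match matter, and ties go to the most recent node. Readout
is $G \cdot a \cdot$ snapshot: excitatory on snapshot-active units and
inhibitory on the rest.

With the default binding rate $\eta = 0.1$ and $N = 64$, a $k:1$
presentation asymmetry gives a long-term-memory margin of
$(k-1)\,\eta N$ toward the old place; the default high gain $G = 20$
exceeds the $k = 4$ margin ($2 \eta N = 12.8$ plus the opposing one-hot
inhibition), so the A-not-B answer flips from A to B — deterministically,
at every seed. With $k = 1$ the two bindings tie exactly and the
winner-take-all tie rule (lowest index) answers A at zero gain; this
tie-rule outcome is asserted as observed behavior in the tests.

### Predictive map and replay

Episodic associations are learned at the attractor-event level: event
$u$ followed by event $v$ adds $\eta_p$ to $S_{uv}$ (adjacent events
only; an episode break learns nothing). Readout is delayed: only after
the state has resided in $u$ for $d = 5$ steps does the map drive the
network toward $u$'s successors, mirroring the delay used at learning.
Two implementation details make replay robust under noise: the
residence clock uses a looser overlap threshold (0.75) than event
logging, and once an association fires its drive stays latched until
the state lands in a different attractor (or $4d$ steps pass). Without
the latch, a noise fluctuation part-way through a driven transition
would cut the drive and strand the state between patterns.

## Stimulus generators

* `make_letter_patterns()` — L, X and + on a 5×5 grid (9 active cells
  each, mildly correlated); the pattern-completion fixture.
* `make_semantic_triplet(64, 20, 8)` — X, Y, Z with 20 active features
  each; X∩Y and Y∩Z share 8, X∩Z share none. "Semantically related"
  means feature overlap.
* `make_pairwise_patterns(labels, s)` — one dedicated $s$-unit block
  per unordered pair of patterns, active in exactly those two. Every
  pattern has the same activity, every pair the same small overlap, so
  Hebbian storage gives uniform attractor depths. The episode-chain
  tasks use this set because sampled random sets at $K = 6$–$7$
  patterns have unequal margins (in unlucky draws a chain member is not
  even a fixed point) and would bias replay.
* `place_codes()` — orthogonal one-hot place codes.

What the generators deliberately do **not** emulate: graded feature
values, sensory noise in the stimulus itself, population-coded places,
or stimulus similarity structure beyond controlled feature sharing.
Passing tests therefore show that the *architecture* produces the
qualitative phenomena under clean, controlled inputs — not that it
would survive raw sensory data; a perceptual front end is explicitly
out of scope.

## Study conditions and calibration

No quantitative parameter values accompany the original qualitative
simulations, so the package fixes its own and freezes them (they are
the task defaults, not tuning knobs). Problem sizes were chosen for
desk-scale determinism: WHAT $N = 64$ (25 for letters, 60/63 for the
chain sets), 8 place units, working-memory capacity 16.

| Task | Condition | Values |
|---|---|---|
| wandering, low noise | related transitions only | $\sigma=0.2$, $U=0.10$, $\beta=3$, $\tau_{rec}=40$, 4500 steps |
| wandering, high noise | unrelated hops appear | $\sigma=0.48$, $U=0$, $\beta=3$, 7000 steps |
| wandering, no noise | leave and return | $\sigma=0$, $U=0.05$, $\beta=3$, 2000 steps |
| episodic replay | exact sequences | $\sigma=0$, $\beta=\infty$, $U=0$, $g_{td}=2.5$, $d=5$ |
| episodic reverie | chain blending | $\sigma=0.45$, otherwise as replay, 500 runs × 250 steps |
| VTE | route simulation | as replay, 7-pattern set |

The elevated reverie noise was calibrated once by bracketing: at
$\sigma = 0.45$ the exact blended sequence X,Y,Z,Q,R occurs in roughly
3–8% of 250-step runs (measured over several disjoint seed blocks), so
500 runs observe at least one crossover with near certainty, while zero
noise still replays both chains exactly. The high-noise wandering level
$\sigma = 0.48$ sits just below the cliff where attractor events stop
forming; above it the state degenerates into mixtures and nothing is
logged. The high-noise condition runs without depression for the same
reason: depression plus strong noise prevents any event from reaching
the 0.9/3-step detection criterion.

The noise-sweep property (blend counts nondecreasing in $\sigma$) is
asserted in the tests over a 3-point sweep with 25 pooled runs per
point; the acceptance-level checks use the full 500-run condition.

## Numerical conventions

* $\operatorname{sign}(0)$ keeps the previous activation; WTA and label
  ties break to the lowest index / first stored pattern. All
  randomness flows through R's RNG, so a seed fixes every trajectory
  bit-for-bit.
* Partial cues encode unknown units as 0, never $-1$: absence of
  evidence is not evidence of absence. The comparator counts only
  strict sign disagreements, so an empty state produces zero surprise
  against any first stimulus (it recruits working memory but does not
  trigger a reset).
* $\theta_{reset} = 0.5$: a reset fires when more than half the
  attended features mismatch. Uncorrelated stimuli sit exactly at 0.5
  and do not reset; the strong bottom-up weight ($g_{bu} = 2$) lets
  perception re-settle correctly either way.
* The covariance storage rule divides by the mean per-unit variance of
  the centered set, putting its fields on the same scale as the
  Hebbian rule.

## Known limitations

* Deterministic depression-only escape is impossible in this coding
  (see above); wandering regimes need finite gain or input noise.
* The middle member of the semantic triplet is the most stable
  attractor (it overlaps both neighbors), so low-noise wandering is
  dominated by leave-and-return excursions around it with occasional
  related hops, rather than by steady X→Y→Z circulation.
* Sequence blending is only observed at the junction the noise happens
  to find; the model has no mechanism to prefer goal-relevant blends.
* Value/emotion coupling, action selection, saliency-based attention
  and any sensory front end are out of scope.
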