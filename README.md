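# beechoreo

Analysis of head–thorax choreography in freely flying insects.

Flying insects such as bumblebees (*Bombus terrestris*) structure their
flights into brief, fast turns (**saccades**) separated by stretches of nearly
constant heading (**intersaccades**), during which translational optic flow
carries distance information. The head and thorax execute this choreography
together but not identically: the thorax begins turning earlier and more
slowly, the head later and faster. Most tracking setups, however, resolve only
the thorax. `beechoreo` provides the analysis chain needed to study this
coordination from marker-based motion capture, and to predict what the head is
doing when only the thorax was recorded:

1. **Kinematics** — rigid-body orientation from three tracked markers per body
   part: body frame from the marker triangle, Euler angles under the
   yaw-pitch-roll convention (`R = Rz(ψ) Ry(θ) Rx(φ)`), penalized cubic
   smoothing splines with a target effective degrees of freedom (default
   λ = 150), and body-frame angular velocity
   `ω = unskew(Rᵀ dR/dt)` about the body z-axis. Degraded recordings can be
   emulated (decimate-and-respline frame-rate round trips; top-view
   flattening with the null-pitch/roll assumption).
2. **Segmentation** — two-threshold (hysteresis) saccade extraction: frames
   with |ω_z| > 372.42 °/s seed a saccade, which extends over contiguous
   frames with |ω_z| > 200.54 °/s. The frame-wise accuracy between two
   labelings is `ACC = (1/N) Σ_t [C(t) = H(t)]` (Iverson bracket), and a
   benchmark thorax double threshold can be optimized exhaustively against
   head ground truth.
3. **Saccade classifier** — decision trees and random forests predict the
   head's saccade state at time *t* from the windowed thorax velocity
   `Ω_z(t) = [ω_z(t−Δt/2), …, ω_z(t+Δt/2)]`, with grid search over depth
   D ∈ [1, 20] and window Δt ∈ [0, 50] ms on a chronological 70/30 split and a
   held-out test flight.
4. **Velocity mapper** — a three-layer network (velocity window + bias → N
   relu units + bias → 2 tanh outputs encoding (cos θ, sin θ) of the predicted
   angular velocity) maps one body part's velocity to the other's. It is
   trained with Adam for 30 epochs under the anti-identity loss

   ```
   L = Σ_t |enc_head(t) − O(t)|² / ( λ |enc_thorax(t) − O(t)|² + ϵ ),
   ```

   λ = 0.5, ϵ = 0.1, which is zero when the output matches the target and
   maximal when the network merely reproduces its input. Temporal-shift
   (forecast τ < 0 / backcast τ > 0) scans of the correlation between decoded
   prediction and target probe the direction of information flow between head
   and thorax (a predictive-causality reading).
5. **Synthetic flights** — a generator with known ground truth (renewal
   saccade events, Gaussian velocity pulses with equal head/thorax integrals,
   configurable thorax lead, Ornstein–Uhlenbeck measurement noise, rigid
   equilateral marker triangles) so that every stage is testable end to end.

The intended users are researchers in computational ethology and insect
flight control working with high-speed marker tracking.

## Worked example

Six synthetic learning flights; thorax-threshold benchmark versus a windowed
random forest on the held-out sixth flight; then the thorax→head mapper.

```r
library(beechoreo)

flights <- lapply(1:6, function(i)
  generate_flight(flight_config(duration = 10, seed = 100 + i)))
flights[[1]]
#> <synthetic_flight: 10.0 s @ 500 fps, 43 saccade events, 20.2% saccade frames>

sp <- split_flights(lapply(flights, function(f)
  list(v = f$thorax_v, labels = f$true_labels)))

## benchmark: optimal double threshold on the thorax (training frames)
opt <- optimize_benchmark_thresholds(
  unlist(lapply(sp$train, function(f) f$v$omega_z)),
  unlist(lapply(sp$train, function(f) f$labels$labels)))
c(opt$high, opt$low)                       # 330, 300 deg/s
bench <- two_threshold_segment(sp$test[[1]]$v, opt$high, opt$low)
label_accuracy(bench, sp$test[[1]]$labels) # 0.931 on the held-out flight

## classifier: random forest on 20 ms thorax windows
spec <- window_spec(20, 500)
rf <- train_classifier(windows_for_flights(sp$train, spec),
                       "random_forest", depth = 10, seed = 1)
evaluate_classifier(rf, windows_for_flights(sp$test, spec))
#> accuracy 0.973, error_rate 0.027, auc 0.996
```

The forest reads the temporal context that a fixed threshold cannot: on the
held-out flight it misclassifies 2.7 % of frames where the optimized
benchmark misclassifies 6.9 % — the same qualitative ordering reported for
real bumblebee recordings, where windowed classifiers cut the benchmark's
misclassification by roughly a third.

```r
## thorax -> head velocity mapper (tau = 0)
m <- train_mapper(lapply(flights[1:5], `[[`, "thorax_v"),
                  lapply(flights[1:5], `[[`, "head_v"),
                  mapper_config(n_hidden = 32, delta_t_ms = 29, seed = 1))
m
#> <velocity_mapper: N=32, window 29 ms, tau 0 ms; final training loss 0.0002>
pred <- predict(m, flights[[6]]$thorax_v, flights[[6]]$head_v)
cor(pred$pred_omega, pred$target_omega)    # 0.948 on the held-out flight
```

A temporal-shift scan (`correlation_vs_shift()`) retrains the mapper per shift
τ and reports r(τ); on synthetic flights where the head leads the thorax by
10 ms, the head→thorax curve peaks at τ = −10 ms (forecasting) and falls off
sharply on the backcasting side.

There is also a one-shot pipeline and a command-line wrapper:

```sh
Rscript inst/cli/choreo.R --stages simulate,segment,benchmark,train-clf \
    --seed 1 --n-flights 6 --out runs/demo
```

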