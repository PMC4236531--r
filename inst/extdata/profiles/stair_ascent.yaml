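# Stair ascent, one stride on a 20 cm step.  The plantarflexion moment peaks
# in the single-support push-off window around 55-65% of the cycle.
activity: stair_ascent
cyclic: true
duration: 1.4
sampling_rate: 100
noise_sd: 0.0
angles:
  hip:
    mean: -0.45
    harmonics:
      - {order: 1, amp: 0.45, phase: 3.14159}
  knee:
    mean: -0.75
    harmonics:
      - {order: 1, amp: 0.65, phase: 3.770}
  ankle:
    mean: 0.05
    harmonics:
      - {order: 1, amp: 0.28, phase: 4.40}
      - {order: 2, amp: 0.13, phase: 2.97}
moments:
  ankle:
    - {center: 0.60, width: 0.09, amp: 1.68}
    - {center: 0.05, width: 0.05, amp: -0.05}
  knee:
    - {center: 0.16, width: 0.10, amp: 1.30}
    - {center: 0.65, width: 0.07, amp: -0.40}
  hip:
    - {center: 0.10, width: 0.10, amp: 0.91}
    - {center: 0.70, width: 0.10, amp: -0.35}
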