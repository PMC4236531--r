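# Stair descent, one stride on a 20 cm step; large eccentric ankle and knee
# moments during controlled lowering.
activity: stair_descent
cyclic: true
duration: 1.3
sampling_rate: 100
noise_sd: 0.0
angles:
  hip:
    mean: -0.25
    harmonics:
      - {order: 1, amp: 0.30, phase: 3.14159}
  knee:
    mean: -0.65
    harmonics:
      - {order: 1, amp: 0.55, phase: 3.80}
  ankle:
    mean: 0.05
    harmonics:
      - {order: 1, amp: 0.38, phase: 1.13}
      - {order: 2, amp: 0.05, phase: 4.00}
moments:
  ankle:
    - {center: 0.20, width: 0.10, amp: 1.60}
    - {center: 0.75, width: 0.06, amp: -0.08}
  knee:
    - {center: 0.30, width: 0.12, amp: 1.31}
    - {center: 0.72, width: 0.08, amp: 0.55}
  hip:
    - {center: 0.10, width: 0.08, amp: 0.60}
    - {center: 0.60, width: 0.10, amp: -0.30}
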