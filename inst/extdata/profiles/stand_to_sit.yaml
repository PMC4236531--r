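# Stand-to-sit onto a chair at knee height; mirror of sit-to-stand with
# slightly lower eccentric extensor peaks.
activity: stand_to_sit
cyclic: false
duration: 2.4
sampling_rate: 100
noise_sd: 0.0
angles:
  hip:   {start: -0.05, end: -1.50, center: 1.2, width: 0.30}
  knee:  {start: -0.12, end: -1.50, center: 1.2, width: 0.30}
  ankle: {start:  0.05, end: -0.15, center: 1.2, width: 0.30}
moments:
  knee:
    - {center: 0.52, width: 0.10, amp: 0.80}
  hip:
    - {center: 0.50, width: 0.10, amp: 0.70}
  ankle:
    - {center: 0.45, width: 0.12, amp: 0.35}
    - {center: 0.75, width: 0.08, amp: -0.08}
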