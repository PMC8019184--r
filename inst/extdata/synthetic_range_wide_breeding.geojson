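{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[0,2600],[600,2450],[1400,2500],[2200,2400],[3000,2550],[3200,3000],[3100,3700],[2600,4100],[1800,4200],[900,4100],[300,3800],[-100,3200],[0,2600]]]}}
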