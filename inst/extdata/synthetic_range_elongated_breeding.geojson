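{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[0,3150],[800,3050],[1700,3150],[2600,3050],[3500,3150],[4400,3080],[5000,3200],[5050,3550],[4300,3650],[3400,3550],[2500,3680],[1600,3560],[700,3650],[-50,3500],[0,3150]]]}}
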