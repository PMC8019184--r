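{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[400,300],[1300,200],[2300,330],[3300,230],[4200,350],[5100,260],[5500,450],[5450,780],[4600,880],[3600,760],[2600,900],[1600,780],[800,880],[350,620],[400,300]]]}}
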