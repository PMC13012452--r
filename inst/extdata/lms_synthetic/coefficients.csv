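"sex","index","a0","a1","a2","b0","b1","L"
"male","FVC",-8.634,2.1,-0.15,-2.433,0.08,0.9
"male","FEV1",-8.457,2.05,-0.19,-2.433,0.08,0.9
"male","FEV1_FVC",0.166,0,-0.087,-2.737,0.02,1.2
"male","PEF",-5.122,1.5,-0.1,-2.303,0.05,1
"male","FEF25_75",-7.006,1.9,-0.35,-1.966,0.05,0.8
"male","FEF75",-5.684,1.6,-0.5,-1.772,0.05,0.7
"female","FVC",-8.73936051565783,2.1,-0.15,-2.433,0.08,0.9
"female","FEV1",-8.56236051565783,2.05,-0.19,-2.433,0.08,0.9
"female","FEV1_FVC",0.166,0,-0.087,-2.737,0.02,1.2
"female","PEF",-5.22736051565783,1.5,-0.1,-2.303,0.05,1
"female","FEF25_75",-7.11136051565783,1.9,-0.35,-1.966,0.05,0.8
"female","FEF75",-5.78936051565783,1.6,-0.5,-1.772,0.05,0.7
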