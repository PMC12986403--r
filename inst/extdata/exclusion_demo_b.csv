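PreopSphere,PreopCylinder,PreopAxis,PreopVertex,TargetSphere,TargetCylinder,TargetAxis,TargetVertex,PostopSphere,PostopCylinder,PostopAxis,PostopVertex
-0.75,-1.00,15,12,0,0,0,12,0.00,-0.25,20,12
-1.25,-0.50,80,12,0,0,0,12,-0.25,-0.25,85,12
-1.75,-1.25,160,12,0,0,0,12,-0.50,-0.25,155,12
-1.50,-0.75,40,12,0,0,0,12,-0.25,0.00,0,12
-0.50,-1.50,55,12,0,0,0,12,-0.25,-0.50,60,12
-2.25,-1.75,10,12,0,0,0,12,-0.50,-0.25,5,12
-1.00,-1.00,70,12,0,0,0,12,-0.25,-0.25,75,12
-0.75,-2.00,125,12,0,0,0,12,0.00,-0.50,120,12
-1.25,-0.75,25,12,0,0,0,12,-0.50,-0.25,30,12
-1.75,-1.50,145,12,0,0,0,12,-0.25,-0.25,140,12
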